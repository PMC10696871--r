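# Morphometric similarity network (MSN) construction.
#
# A subject's MSN edge (i, j) is the Pearson correlation between the
# morphometric feature vectors of regions i and j, computed after each feature
# has been z-normalized across regions. No thresholding is ever applied.

#' Canonical morphometric feature names
#'
#' The five T1-derived features used throughout: surface area, cortical
#' thickness, gray matter volume, Gaussian curvature, mean curvature.
#' @export
msn_features <- function() {
  c("surface_area", "cortical_thickness", "gray_matter_volume",
    "gaussian_curvature", "mean_curvature")
}

#' Z-normalize a subject's morphometric table across regions
#'
#' Each feature column is centred and scaled to unit sample standard deviation
#' (ddof = 1) across regions, so features measured in incommensurate units
#' contribute equally to the similarity computation. Affine rescalings of a
#' raw feature are absorbed entirely by this step.
#'
#' @param table numeric region x feature matrix (no missing values).
#' @return matrix of the same shape with columns of mean 0 and sample SD 1.
#' @export
znormalize_features <- function(table) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("morphometric table contains missing values")
  if (nrow(table) < 2) stop("need at least 2 regions")
  s <- apply(table, 2, stats::sd)
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    nm <- colnames(table)[bad] %||% which(bad)
    stop("zero-variance feature(s) across regions: ", paste(nm, collapse = ", "))
  }
  sweep(sweep(table, 2, colMeans(table)), 2, s, "/")
}

#' Build a morphometric similarity network
#'
#' Pairwise Pearson correlations between region feature vectors of a
#' z-normalized morphometric table. With the standard 5 features each
#' correlation is computed over 5 paired values; no small-sample correction
#' and no thresholding are applied. The diagonal is stored as 1 but is
#' excluded from every downstream summary.
#'
#' @param ztable z-normalized region x feature matrix (see
#'   [znormalize_features()]).
#' @return symmetric R x R correlation matrix.
#' @export
build_msn <- function(ztable) {
  ztable <- as.matrix(ztable)
  if (ncol(ztable) < 2) stop("need at least 2 features")
  row_sd <- apply(ztable, 1, stats::sd)
  bad <- !is.finite(row_sd) | row_sd == 0
  if (any(bad)) {
    nm <- rownames(ztable)[bad] %||% which(bad)
    stop("region(s) with constant feature vector, correlation undefined: ",
         paste(utils::head(nm, 5), collapse = ", "))
  }
  net <- stats::cor(t(ztable))
  diag(net) <- 1
  # enforce exact symmetry against floating-point asymmetry
  net <- (net + t(net)) / 2
  net
}

#' Regional MSN strength
#'
#' Strength of region i is the mean correlation between i and all other
#' regions (diagonal excluded); the global strength is the mean of the
#' regional values.
#'
#' @param net MSN correlation matrix.
#' @return list with `regional` (named numeric vector) and `global` (scalar).
#' @export
msn_strength <- function(net) {
  net <- as.matrix(net)
  r <- nrow(net)
  if (r < 2 || ncol(net) != r) stop("need a square matrix with R >= 2")
  regional <- (rowSums(net) - diag(net)) / (r - 1)
  names(regional) <- rownames(net)
  list(regional = regional, global = mean(regional))
}

#' Strength matrix for a cohort
#'
#' Runs z-normalization, MSN construction, and strength extraction for every
#' subject of a cohort.
#'
#' @param features named list of region x feature matrices, one per subject.
#' @return subject x region matrix of MSN strengths.
#' @export
cohort_strengths <- function(features) {
  stopifnot(is.list(features), length(features) >= 1)
  out <- t(vapply(features, function(m) {
    msn_strength(build_msn(znormalize_features(m)))$regional
  }, numeric(nrow(features[[1]]))))
  rownames(out) <- names(features)
  out
}

#' Aggregate regional strengths into labelled networks
#'
#' Unweighted mean of member regions' strengths, per subject and network
#' label (e.g. Yeo-7 functional networks or von Economo classes).
#'
#' @param strengths subject x region strength matrix.
#' @param labels vector of network labels, one per region.
#' @return subject x network matrix (columns sorted by label).
#' @export
network_aggregate <- function(strengths, labels) {
  strengths <- as.matrix(strengths)
  if (length(labels) != ncol(strengths))
    stop("one label per region required")
  labs <- sort(unique(labels))
  if (anyNA(labels)) stop("labels must not be missing")
  out <- sapply(labs, function(l) {
    idx <- which(labels == l)
    rowMeans(strengths[, idx, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(strengths),
                dimnames = list(rownames(strengths), as.character(labs)))
  out
}
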