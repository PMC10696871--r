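# AHBA-style expression preprocessing: probe filtering, probe-to-gene
# collapse, sample-to-region assignment, scaled-robust-sigmoid normalization,
# and assembly of the left-hemisphere region x gene matrix.

#' Construct a probe-level expression container
#'
#' Bundles the pieces an AHBA-style preprocessing run needs: a probe x sample
#' expression matrix, a probe-to-gene map, per-probe per-sample
#' above-background flags, and sample coordinates.
#'
#' @param expr probe x sample numeric matrix (rownames = probe ids).
#' @param probe2gene named character vector probe id -> gene symbol.
#' @param above_bg logical matrix, same shape as `expr`: TRUE where the
#'   measurement exceeded background noise.
#' @param coords sample x 3 coordinate matrix (mm).
#' @param donor optional donor id per sample.
#' @return list of class `probe_matrix`.
#' @export
probe_matrix <- function(expr, probe2gene, above_bg, coords, donor = NULL) {
  expr <- as.matrix(expr)
  above_bg <- as.matrix(above_bg)
  stopifnot(identical(dim(expr), dim(above_bg)), is.logical(above_bg))
  if (is.null(rownames(expr))) stop("expr needs probe ids as rownames")
  if (!all(rownames(expr) %in% names(probe2gene)))
    stop("every probe must appear in probe2gene")
  coords <- as.matrix(coords)
  if (nrow(coords) != ncol(expr)) stop("one coordinate row per sample required")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  structure(list(expr = expr, probe2gene = probe2gene[rownames(expr)],
                 above_bg = above_bg, coords = coords,
                 donor = donor %||% rep("D1", ncol(expr))),
            class = "probe_matrix")
}

#' Filter low-intensity probes
#'
#' A probe is excluded when it falls below background noise in strictly more
#' than 50\% of samples (below-background fraction must be <= 0.5 to keep).
#'
#' @param pm a [probe_matrix()].
#' @return filtered `probe_matrix` (may be empty, with a warning).
#' @export
filter_probes <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  frac_below <- rowMeans(!pm$above_bg)
  keep <- frac_below <= 0.5
  if (!any(keep)) warning("no probes survive the background filter")
  pm$expr <- pm$expr[keep, , drop = FALSE]
  pm$above_bg <- pm$above_bg[keep, , drop = FALSE]
  pm$probe2gene <- pm$probe2gene[keep]
  pm
}

#' Collapse probes to genes by regional homogeneity
#'
#' For genes targeted by multiple probes, keeps the probe whose expression
#' profile has the highest mean Pearson correlation with the gene's other
#' probes (a differential-stability-style homogeneity score); single-probe
#' genes pass through. Genes whose probes are all constant are dropped with
#' a message.
#'
#' @param pm filtered [probe_matrix()].
#' @return gene x sample matrix.
#' @export
collapse_probes_to_genes <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  genes <- split(rownames(pm$expr), pm$probe2gene[rownames(pm$expr)])
  rows <- lapply(names(genes), function(g) {
    probes <- genes[[g]]
    sub <- pm$expr[probes, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    ok <- sds > 0
    if (!any(ok)) {
      message("dropping gene with all-constant probes: ", g)
      return(NULL)
    }
    sub <- sub[ok, , drop = FALSE]
    if (nrow(sub) == 1) return(sub[1, ])
    cm <- stats::cor(t(sub))
    homog <- (rowSums(cm) - 1) / (nrow(sub) - 1)  # mean cor with other probes
    sub[which.max(homog), ]
  })
  keep <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(genes)[keep]
  out
}

#' Assign samples to parcellation regions
#'
#' Synthetic stand-in for boundary-based assignment: each region is a sphere
#' of radius `region_radius` around its scaled centroid; a sample is assigned
#' to the region whose boundary is nearest, provided that distance is at most
#' `max_dist` (samples inside a region have boundary distance 0).
#'
#' @param coords sample x 3 matrix (mm).
#' @param parcellation_left left-hemisphere parcellation rows.
#' @param max_dist assignment tolerance in mm (default 2, the standard
#'   AHBA-mapping tolerance).
#' @param brain_radius scale from unit-sphere centroids to mm (default 70).
#' @param region_radius region sphere radius in mm; default tiles the
#'   brain-sphere surface area across regions.
#' @return integer vector of region ids (NA = unassigned); the unassigned
#'   fraction is reported in a message.
#' @export
assign_samples <- function(coords, parcellation_left, max_dist = 2,
                           brain_radius = 70, region_radius = NULL) {
  coords <- as.matrix(coords)
  cent <- parcellation_centroids(parcellation_left) * brain_radius
  region_radius <- region_radius %||% (2 * brain_radius / sqrt(nrow(cent)))
  d2 <- outer(rowSums(coords^2), rep(1, nrow(cent))) -
    2 * coords %*% t(cent) + outer(rep(1, nrow(coords)), rowSums(cent^2))
  bdist <- abs(sqrt(pmax(d2, 0)) - region_radius)
  bdist[sqrt(pmax(d2, 0)) <= region_radius] <- 0
  nearest <- max.col(-bdist, ties.method = "first")
  dist_near <- bdist[cbind(seq_len(nrow(coords)), nearest)]
  out <- ifelse(dist_near <= max_dist,
                as.integer(rownames(cent))[nearest], NA_integer_)
  message(sprintf("%d/%d samples unassigned (> %g mm from any boundary)",
                  sum(is.na(out)), length(out), max_dist))
  out
}

#' Scaled robust sigmoid normalization
#'
#' Maps a vector through a median/IQR-parameterized sigmoid,
#' `s = 1 / (1 + exp(-(x - median) / (IQR / 1.35)))`, then rescales to
#' `[0, 1]`. The 1.35 divisor converts the IQR into a robust SD estimate;
#' the transform is invariant to positive affine maps of the input and
#' preserves rank order.
#'
#' @param x numeric vector (>= 3 values, positive IQR).
#' @param name label used in the zero-IQR error message.
#' @return vector in `[0, 1]` with min 0 and max 1.
#' @export
srs_normalize <- function(x, name = "input") {
  if (length(x) < 3) stop("need >= 3 values")
  iqr <- stats::IQR(x, type = 7)
  if (iqr == 0) stop("zero IQR, cannot SRS-normalize: ", name)
  s <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  (s - min(s)) / (max(s) - min(s))
}

#' Assemble the left-hemisphere region x gene expression matrix
#'
#' Averages each gene's samples within their assigned regions, drops
#' right-hemisphere regions and unassigned samples, and applies scaled-
#' robust-sigmoid normalization per gene across regions. Genes constant
#' across regions are dropped with a message.
#'
#' @param gene_by_sample gene x sample matrix (from
#'   [collapse_probes_to_genes()]).
#' @param assignment region id per sample (NA = unassigned), from
#'   [assign_samples()].
#' @param parcellation full parcellation (used to restrict to the left
#'   hemisphere).
#' @return region x gene matrix of class `expression_matrix`, values in
#'   `[0, 1]`, rownames = region ids.
#' @export
build_region_gene_matrix <- function(gene_by_sample, assignment, parcellation) {
  gene_by_sample <- as.matrix(gene_by_sample)
  if (ncol(gene_by_sample) != length(assignment)) stop("one assignment per sample")
  left_ids <- parcellation$region_id[parcellation$hemisphere == "left"]
  ok <- !is.na(assignment) & assignment %in% left_ids
  if (length(unique(assignment[ok])) < 2)
    stop("need assigned samples in >= 2 left-hemisphere regions")
  f <- factor(assignment[ok])
  sums <- gene_by_sample[, ok, drop = FALSE] %*%
    stats::model.matrix(~ f - 1)
  counts <- as.vector(table(f))
  reg_gene <- t(sweep(sums, 2, counts, "/"))
  rownames(reg_gene) <- levels(f)
  keep <- apply(reg_gene, 2, function(v) stats::sd(v) > 0)
  dropped <- colnames(reg_gene)[!keep]
  if (length(dropped))
    message("dropping constant gene(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) " ..." else "")
  reg_gene <- reg_gene[, keep, drop = FALSE]
  out <- apply(reg_gene, 2, srs_normalize)
  rownames(out) <- rownames(reg_gene)
  class(out) <- c("expression_matrix", class(out))
  out
}
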