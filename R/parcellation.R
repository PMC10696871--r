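#' Build a synthetic cortical parcellation
#'
#' Generates a stand-in for a high-resolution cortical parcellation (by default
#' 308 regions, 152 on the left hemisphere, the scale used for back-tracked
#' Desikan-Killiany subdivisions). Each hemisphere receives its own set of
#' quasi-uniform spherical centroids from a Fibonacci lattice -- mirroring how
#' FreeSurfer inflates each hemisphere to a full sphere -- so spin permutation
#' tests can rotate hemispheres independently (mirrored for the right).
#' Functional (Yeo-7) and cytoarchitectonic (von Economo) labels are assigned
#' in contiguous index blocks within each hemisphere, and regions are grouped
#' into parent Desikan-Killiany-style areas.
#'
#' @param n_regions total number of regions (default 308).
#' @param n_left number of left-hemisphere regions (default 152).
#' @param seed integer seed; controls the random orientation of each
#'   hemisphere's lattice so different seeds give different (but reproducible)
#'   geometries.
#' @return a `data.frame` of class `parcellation` with columns `region_id`,
#'   `name`, `hemisphere`, `x`, `y`, `z` (unit-sphere centroid), `yeo7`,
#'   `voneconomo`, `parent_dk`.
#' @examples
#' p <- make_parcellation(8, 4, seed = 1)
#' nrow(p)
#' @export
make_parcellation <- function(n_regions = 308L, n_left = 152L, seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_left <- as.integer(n_left)
  if (is.na(n_regions) || is.na(n_left) || n_left < 2L || n_left >= n_regions)
    stop("need 2 <= n_left < n_regions")
  n_right <- n_regions - n_left
  if (n_right < 2L) stop("right hemisphere needs at least 2 regions")

  with_seed(seed, {
    cl <- fibonacci_sphere(n_left) %*% random_rotation()
    cr <- fibonacci_sphere(n_right) %*% random_rotation()
  })
  centroid <- rbind(cl, cr)
  hemisphere <- rep(c("left", "right"), c(n_left, n_right))
  within_idx <- c(seq_len(n_left), seq_len(n_right))

  # contiguous label blocks per hemisphere
  block_label <- function(i, n, k) pmin(k, 1L + ((i - 1L) * k) %/% n)
  yeo7 <- ifelse(hemisphere == "left",
                 block_label(within_idx, n_left, 7L),
                 block_label(within_idx, n_right, 7L))
  vone <- ifelse(hemisphere == "left",
                 block_label(((within_idx + 3L - 1L) %% n_left) + 1L, n_left, 7L),
                 block_label(((within_idx + 3L - 1L) %% n_right) + 1L, n_right, 7L))
  n_parent <- max(2L, min(34L, n_left %/% 4L))
  parent <- ifelse(hemisphere == "left",
                   paste0("L_DK", block_label(within_idx, n_left, n_parent)),
                   paste0("R_DK", block_label(within_idx, n_right, n_parent)))

  out <- data.frame(
    region_id = seq_len(n_regions),
    name = paste0(ifelse(hemisphere == "left", "L_", "R_"),
                  formatC(within_idx, width = 3, flag = "0")),
    hemisphere = hemisphere,
    x = centroid[, 1], y = centroid[, 2], z = centroid[, 3],
    yeo7 = as.integer(yeo7),
    voneconomo = as.integer(vone),
    parent_dk = parent,
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcellation", "data.frame")
  validate_parcellation(out)
  out
}

#' Validate a parcellation table
#'
#' Checks the structural invariants every parcellation consumer assumes:
#' unique contiguous `region_id`, unit-norm centroids, both hemispheres
#' non-empty.
#'
#' @param p a parcellation `data.frame`.
#' @return `p`, invisibly; stops on violation.
#' @export
validate_parcellation <- function(p) {
  need <- c("region_id", "name", "hemisphere", "x", "y", "z", "yeo7", "voneconomo")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("parcellation missing columns: ", paste(miss, collapse = ", "))
  if (!identical(as.integer(p$region_id), seq_len(nrow(p))))
    stop("region_id must be 1..n, contiguous")
  nrm <- sqrt(p$x^2 + p$y^2 + p$z^2)
  if (any(abs(nrm - 1) > 1e-9)) stop("centroids must be unit vectors")
  if (!all(c("left", "right") %in% p$hemisphere))
    stop("both hemispheres must be non-empty")
  invisible(p)
}

#' Extract centroid matrix from a parcellation
#'
#' @param p parcellation.
#' @param hemisphere optional `"left"` or `"right"` to subset.
#' @return numeric matrix with one row per region (rownames = region_id).
#' @export
parcellation_centroids <- function(p, hemisphere = NULL) {
  if (!is.null(hemisphere)) p <- p[p$hemisphere == hemisphere, , drop = FALSE]
  m <- as.matrix(p[, c("x", "y", "z")])
  rownames(m) <- p$region_id
  m
}
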