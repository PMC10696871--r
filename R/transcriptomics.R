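# Imaging transcriptomics: PLS1 linking regional gene expression to
# case-control t-maps, permutation and spin inference, bootstrap gene Z
# scores, thresholded gene lists, ISH gene screening, and cross-disorder
# DGE correlations.

#' First partial-least-squares component for a univariate response
#'
#' For a single response the PLS1 weight vector is proportional to the
#' covariance vector `X'y` (normalized to unit length); region scores are
#' `X w`, and the explained variance is the squared Pearson correlation of
#' the scores with the response. The sign convention flips weights so that
#' `cor(scores, y) >= 0`. Fitted by this closed form rather than iterative
#' NIPALS, whose first component it equals.
#'
#' @param X region x gene matrix.
#' @param y response map over regions (e.g. case-control t values).
#' @param scale_genes z-score each gene across regions first (default TRUE;
#'   required for weight comparability between genes).
#' @return object of class `pls1_result`: `weights` (named, unit length),
#'   `scores`, `explained_variance`, `y`.
#' @export
pls1 <- function(X, y, scale_genes = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (stats::sd(y) == 0) stop("zero-variance response")
  if (scale_genes) X <- zscore_cols(X, fill0 = TRUE)
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("X'y is identically zero")
  w <- w / nw
  scores <- drop(X %*% w)
  r <- stats::cor(scores, y)
  if (r < 0) {
    w <- -w; scores <- -scores; r <- -r
  }
  structure(list(weights = stats::setNames(w, colnames(X)),
                 scores = stats::setNames(scores, rownames(X)),
                 explained_variance = r^2, y = y),
            class = "pls1_result")
}

#' Permutation p value for the PLS1 association
#'
#' Tests whether the variance of the response explained by PLS1 exceeds
#' chance, either by spherical rotation of the response map (`mode =
#' "spin"`, preserving spatial autocorrelation) or by plain shuffling.
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param X region x gene matrix.
#' @param y response map.
#' @param n_perm number of permutations (>= 100; the reference analysis
#'   uses 10,000).
#' @param mode `"spin"` or `"shuffle"`.
#' @param centroids unit-sphere region centroids (required for spin mode).
#' @param seed integer seed.
#' @return scalar p value.
#' @export
pls_permutation_p <- function(X, y, n_perm = 10000L, mode = c("spin", "shuffle"),
                              centroids = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- pls1(X, y)$explained_variance
  Xz <- zscore_cols(as.matrix(X), fill0 = TRUE)
  ev_for <- function(yp) {
    if (stats::sd(yp) == 0) return(0)
    w <- drop(crossprod(Xz, yp - mean(yp)))
    s <- drop(Xz %*% w)
    if (stats::sd(s) == 0) return(0)
    stats::cor(s, yp)^2
  }
  if (mode == "spin") {
    if (is.null(centroids)) stop("spin mode needs centroids")
    perms <- spin_permutations(centroids, n_perm, seed)
    null <- vapply(seq_len(n_perm), function(i) ev_for(y[perms[, i]]), 0)
  } else {
    null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      ev_for(sample(y)), 0))
  }
  (1 + sum(null >= obs)) / (n_perm + 1)
}

# Generate n_rot nearest-centroid relabelling permutations from uniformly
# random rotations of the centroid sphere. The nearest-neighbour map is
# repaired into a bijection (greedy global matching) when rotations produce
# duplicate targets, so each null map is a true permutation of the original
# values. Returns an R x n_rot integer matrix.
spin_permutations <- function(centroids, n_rot, seed) {
  centroids <- as.matrix(centroids)
  R <- nrow(centroids)
  with_seed(seed, {
    out <- matrix(0L, R, n_rot)
    for (i in seq_len(n_rot)) {
      rot <- random_rotation()
      D <- angular_distance(centroids, centroids %*% rot)
      perm <- max.col(-D, ties.method = "first")
      if (anyDuplicated(perm)) perm <- greedy_match(D)
      out[, i] <- perm
    }
    out
  })
}

# Greedy bijective matching on a distance matrix: repeatedly take the
# globally closest unmatched (row, col) pair.
greedy_match <- function(D) {
  R <- nrow(D)
  ord <- order(D)
  perm <- integer(R)
  used_r <- logical(R); used_c <- logical(R)
  n_done <- 0L
  for (k in ord) {
    cc <- ((k - 1L) %/% R) + 1L
    rr <- ((k - 1L) %% R) + 1L
    if (!used_r[rr] && !used_c[cc]) {
      perm[rr] <- cc
      used_r[rr] <- TRUE; used_c[cc] <- TRUE
      n_done <- n_done + 1L
      if (n_done == R) break
    }
  }
  perm
}

#' Spin test for the spatial correlation of two region maps
#'
#' Spearman correlation with a spatial-permutation null: region centroids
#' are rotated by uniformly random 3D rotations and each region relabelled
#' by its nearest rotated centroid (repaired to a bijection), preserving the
#' spatial autocorrelation of the map under the null. Two-sided:
#' `p = (1 + #{|rho_null| >= |rho|}) / (n_rot + 1)`.
#'
#' @param map_a,map_b numeric maps over the same regions.
#' @param centroids unit-sphere centroids of those regions (single
#'   hemisphere; for bilateral maps run per hemisphere with mirrored maps).
#' @param n_rot number of rotations (default 10,000).
#' @param seed integer seed.
#' @return list with `rho` and `p_spin`.
#' @export
spin_test <- function(map_a, map_b, centroids, n_rot = 10000L, seed = 1L) {
  if (length(map_a) != length(map_b)) stop("maps must share the region index")
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop("degenerate (constant) map")
  rho <- stats::cor(map_a, map_b, method = "spearman")
  perms <- spin_permutations(centroids, n_rot, seed)
  ra <- rank(map_a)
  null <- vapply(seq_len(n_rot), function(i)
    stats::cor(ra, rank(map_b[perms[, i]])), 0)
  list(rho = rho, p_spin = (1 + sum(abs(null) >= abs(rho))) / (n_rot + 1))
}

#' Bootstrap standard errors and Z scores for PLS1 gene weights
#'
#' Resamples regions with replacement, refits PLS1 on each bootstrap sample,
#' aligns each bootstrap weight vector's sign to the original (flipped when
#' its correlation with the original weights is negative), and reports
#' `SE = SD` over bootstraps and `Z = weight / SE` per gene.
#'
#' @param X region x gene matrix.
#' @param y response map.
#' @param B number of bootstrap samples (the reference analysis uses
#'   10,000).
#' @param seed integer seed.
#' @return data.frame with `gene`, `weight`, `se`, `z`, ordered by
#'   decreasing weight; genes with zero SE get signed-infinite Z with a
#'   warning.
#' @export
bootstrap_gene_z <- function(X, y, B = 10000L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 10) stop("need >= 10 regions")
  base <- pls1(X, y)
  w0 <- base$weights
  G <- ncol(X)
  with_seed(seed, {
    W <- matrix(0, B, G)
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      if (stats::sd(y[idx]) == 0) {  # degenerate resample: redraw
        idx <- sample.int(nrow(X), replace = TRUE)
        if (stats::sd(y[idx]) == 0) next
      }
      wb <- pls1(X[idx, , drop = FALSE], y[idx])$weights
      if (sum(wb * w0) < 0) wb <- -wb
      W[b, ] <- wb
    }
  })
  se <- apply(W, 2, stats::sd)
  z <- ifelse(se > 0, w0 / se, sign(w0) * Inf)
  if (any(se == 0)) warning("zero bootstrap SE for ", sum(se == 0),
                            " gene(s); Z reported as signed infinity")
  out <- data.frame(gene = names(w0), weight = unname(w0), se = se,
                    z = unname(z), row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$weight), ]
}

#' Threshold bootstrap Z scores into PLS1+/- gene lists
#'
#' `PLS1+ = {Z > 5}`, `PLS1- = {Z < -5}` (strict inequalities), each sorted
#' by decreasing `|Z|`.
#'
#' @param z named numeric vector of gene Z scores (or the data.frame from
#'   [bootstrap_gene_z()]).
#' @return list with `pos` and `neg` character vectors.
#' @export
threshold_gene_lists <- function(z) {
  if (is.data.frame(z)) z <- stats::setNames(z$z, z$gene)
  pos <- z[z > 5]
  neg <- z[z < -5]
  list(pos = names(pos)[order(-abs(pos))],
       neg = names(neg)[order(-abs(neg))])
}

#' Screen a curated gene list against a t-map
#'
#' For each gene of the list present in the expression matrix: Spearman
#' correlation of its regional expression with the t-map, a spin-test p
#' value, and a Benjamini-Hochberg q across the list. A gene is flagged
#' significant when `|rho| > 0.35` and `q < 0.05`.
#'
#' @param expr region x gene expression matrix.
#' @param tmap t values over the same regions.
#' @param gene_list character vector (e.g. ISH disease genes).
#' @param centroids unit-sphere centroids for the spin null.
#' @param n_rot rotations for the spin null (default 10,000).
#' @param seed integer seed.
#' @return data.frame with `gene`, `rho`, `p_spin`, `q`, `significant`.
#' @export
ish_gene_screen <- function(expr, tmap, gene_list, centroids,
                            n_rot = 10000L, seed = 1L) {
  expr <- as.matrix(expr)
  genes <- intersect(gene_list, colnames(expr))
  if (!length(genes)) stop("gene list does not overlap the expression matrix")
  perms <- spin_permutations(centroids, n_rot, seed)
  rt <- rank(tmap)
  rt_perm <- apply(perms, 2, function(p) rt[p])  # ranks of rotated tmap
  res <- lapply(genes, function(g) {
    e <- expr[, g]
    rho <- stats::cor(e, tmap, method = "spearman")
    re <- rank(e)
    null <- stats::cor(re, rt_perm)
    p <- (1 + sum(abs(null) >= abs(rho))) / (n_rot + 1)
    data.frame(gene = g, rho = rho, p_spin = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p_spin)
  out$significant <- abs(out$rho) > 0.35 & out$q < 0.05
  out
}

#' Correlate PLS1 gene weights with cross-disorder differential expression
#'
#' Restricted to the genes of a PLS1 list that a disorder's DGE table
#' reports as upregulated (`log2FC > 0`), computes the Spearman correlation
#' between the PLS1 weights and the log2 fold changes. The null redraws
#' `|overlap|` weights at random from the full background weight vector;
#' two-sided `p = (1 + #{|rho_null| >= |rho|}) / (n_perm + 1)`. Overlaps
#' below 5 genes are flagged `insufficient_overlap` and get no p value.
#'
#' @param list_weights named numeric vector: PLS1 weights of the gene list
#'   under study (e.g. the PLS1- genes).
#' @param dge data.frame with `gene` and `log2fc`.
#' @param background_weights named numeric vector of weights for the full
#'   gene background.
#' @param n_perm permutations (default 10,000).
#' @param seed integer seed.
#' @return one-row data.frame: `n_overlap`, `rho`, `p_perm`,
#'   `insufficient_overlap`.
#' @export
dge_weight_correlation <- function(list_weights, dge, background_weights,
                                   n_perm = 10000L, seed = 1L) {
  up <- dge$gene[dge$log2fc > 0]
  overlap <- intersect(names(list_weights), up)
  m <- length(overlap)
  if (m < 5)
    return(data.frame(n_overlap = m, rho = NA_real_, p_perm = NA_real_,
                      insufficient_overlap = TRUE))
  fc <- dge$log2fc[match(overlap, dge$gene)]
  w <- list_weights[overlap]
  rho <- stats::cor(w, fc, method = "spearman")
  rfc <- rank(fc)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stats::cor(rank(sample(background_weights, m)), rfc), 0))
  p <- (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
  data.frame(n_overlap = m, rho = rho, p_perm = p,
             insufficient_overlap = FALSE)
}

#' Cross-disorder correlation table with FDR adjustment
#'
#' Runs [dge_weight_correlation()] for each disorder's DGE table and adjusts
#' the permutation p values across disorders by Benjamini-Hochberg.
#'
#' @param list_weights,background_weights see [dge_weight_correlation()].
#' @param dge_tables named list of DGE data.frames.
#' @param n_perm,seed see [dge_weight_correlation()].
#' @return data.frame, one row per disorder, with `q` added.
#' @export
dge_weight_correlations <- function(list_weights, dge_tables,
                                    background_weights, n_perm = 10000L,
                                    seed = 1L) {
  rows <- lapply(names(dge_tables), function(d) {
    r <- dge_weight_correlation(list_weights, dge_tables[[d]],
                                background_weights, n_perm,
                                seed = child_seed(seed, match(d, names(dge_tables))))
    cbind(disorder = d, r)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !out$insufficient_overlap
  out$q[ok] <- bh_fdr(out$p_perm[ok])
  out
}

#' Benjamini-Hochberg q values
#'
#' Step-up false-discovery-rate adjustment.
#'
#' @param p vector of p values in `[0, 1]`.
#' @return vector of q values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("invalid p values")
  stats::p.adjust(p, method = "BH")
}
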