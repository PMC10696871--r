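# Regional cell-type scoring by single-sample GSEA and permutation tests
# for the overlap between PLS gene lists and cell-type marker sets.

#' Regional ssGSEA cell-type scores
#'
#' For each region, genes are ranked by expression (descending) and each
#' gene set receives the rank-weighted Kolmogorov-Smirnov running-sum score
#' in its single-sample form: the sum over ranked positions of the
#' difference between the cumulative `|rank|^alpha`-weighted mass of in-set
#' genes and the cumulative uniform mass of out-set genes. Scores are
#' rank-based, hence invariant to strictly monotone transforms of a
#' region's expression profile. A set spanning all genes leaves the out-set
#' mass undefined and raises an error.
#'
#' @param expr region x gene expression matrix.
#' @param gene_sets named list of gene symbol vectors.
#' @param alpha rank-weight exponent (default 0.25, the conventional
#'   single-sample default).
#' @param normalize z-score each cell type's scores across regions
#'   (default FALSE; raw regional scores are reported).
#' @return region x cell-type matrix.
#' @export
ssgsea_region_scores <- function(expr, gene_sets, alpha = 0.25,
                                 normalize = FALSE) {
  expr <- as.matrix(expr)
  G <- ncol(expr)
  genes <- colnames(expr)
  if (is.null(genes)) stop("expr needs gene names as colnames")
  eff_sets <- lapply(gene_sets, function(s) intersect(unique(s), genes))
  small <- vapply(eff_sets, length, 0L) < 2
  if (any(small)) stop("set(s) with < 2 genes in the matrix: ",
                       paste(names(gene_sets)[small], collapse = ", "))
  full <- vapply(eff_sets, length, 0L) >= G
  if (any(full)) stop("set(s) covering every gene (out-set mass undefined): ",
                      paste(names(gene_sets)[full], collapse = ", "))
  out <- matrix(0, nrow(expr), length(eff_sets),
                dimnames = list(rownames(expr), names(eff_sets)))
  for (r in seq_len(nrow(expr))) {
    x <- expr[r, ]
    ord <- order(x, decreasing = TRUE)
    rnk <- G - rank(x, ties.method = "first") + 1  # 1 = most expressed
    wgt <- (G - rnk + 1)^alpha                     # |rank weight|^alpha
    for (si in seq_along(eff_sets)) {
      inset <- genes %in% eff_sets[[si]]
      io <- inset[ord]
      w_ord <- wgt[ord]
      p_in <- cumsum(ifelse(io, w_ord, 0)) / sum(w_ord[io])
      p_out <- cumsum(!io) / (G - sum(io))
      out[r, si] <- sum(p_in - p_out)
    }
  }
  if (normalize) out <- apply(out, 2, zscore)
  out
}

#' Permutation test for gene-list / gene-set overlap
#'
#' Observed statistic: `|list intersect set|`. Null: the overlap of a
#' uniformly drawn background subset of size `|list|` with the set;
#' `p = (1 + #{null >= observed}) / (n_perm + 1)` (upper tail; equals the
#' hypergeometric tail in expectation).
#'
#' @param gene_list character vector (e.g. a PLS1 gene list).
#' @param gene_set character vector (e.g. cell-type markers).
#' @param background gene universe containing both.
#' @param n_perm permutations (default 10,000).
#' @param seed integer seed.
#' @return list with `overlap`, `p_perm`.
#' @export
overlap_permutation_test <- function(gene_list, gene_set, background,
                                     n_perm = 10000L, seed = 1L) {
  gene_list <- unique(gene_list); gene_set <- unique(gene_set)
  if (length(gene_list) > length(background))
    stop("list larger than background")
  if (!all(gene_list %in% background) || !all(gene_set %in% background))
    stop("list and set must be subsets of the background")
  obs <- length(intersect(gene_list, gene_set))
  in_set <- background %in% gene_set
  m <- length(gene_list)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    sum(in_set[sample.int(length(background), m)]), 0L))
  list(overlap = obs, p_perm = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Overlap tests across all cell types with FDR correction
#'
#' Runs [overlap_permutation_test()] of one gene list against each cell-type
#' marker set and adjusts p values across cell types by Benjamini-Hochberg.
#'
#' @param gene_list character vector.
#' @param cell_sets named list of marker sets.
#' @param background gene universe.
#' @param n_perm,seed see [overlap_permutation_test()].
#' @return data.frame with `cell_type`, `overlap`, `p_perm`, `q`.
#' @export
celltype_overlap_tests <- function(gene_list, cell_sets, background,
                                   n_perm = 10000L, seed = 1L) {
  rows <- lapply(seq_along(cell_sets), function(i) {
    r <- overlap_permutation_test(gene_list, cell_sets[[i]], background,
                                  n_perm, seed = child_seed(seed, i))
    data.frame(cell_type = names(cell_sets)[i], overlap = r$overlap,
               p_perm = r$p_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p_perm)
  out
}
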