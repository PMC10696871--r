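# transcriptomic_assoc: PLS1, permutation/spin inference, bootstrap Z,
# gene lists, ISH screen, DGE correlations, FDR.

left_fixture <- function(n = 60, seed = 2) {
  p <- make_parcellation(2 * n, n, seed = seed)
  p[p$hemisphere == "left", ]
}

test_that("pls1 matches the analytic covariance oracle", {
  set.seed(3)
  for (rep in 1:20) {
    X <- matrix(rnorm(20 * 50), 20, 50,
                dimnames = list(NULL, sprintf("g%02d", 1:50)))
    y <- rnorm(20)
    fit <- pls1(X, y)
    Xz <- scale(X)
    w_oracle <- drop(crossprod(Xz, y - mean(y)))
    w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
    cosine <- abs(sum(fit$weights * w_oracle))
    expect_gte(cosine, 1 - 1e-10)
    expect_equal(fit$explained_variance, cor(fit$scores, y)^2,
                 tolerance = 1e-12)
    expect_gte(cor(fit$scores, y), 0)   # sign convention
    expect_equal(sqrt(sum(fit$weights^2)), 1, tolerance = 1e-12)
  }
})

test_that("pls1 limit case and sign flip", {
  # with many regions, chance correlations of the noise genes with y are
  # negligible and the matching gene dominates
  set.seed(4)
  X <- matrix(rnorm(500 * 5), 500, 5, dimnames = list(NULL, letters[1:5]))
  y <- scale(X[, "d"])[, 1]
  fit <- pls1(X, y)
  expect_equal(names(which.max(abs(fit$weights))), "d")
  expect_gte(fit$explained_variance, 0.99)

  flip <- pls1(X, -y)
  expect_equal(flip$explained_variance, fit$explained_variance,
               tolerance = 1e-12)
  expect_equal(unname(flip$scores), unname(-fit$scores), tolerance = 1e-10)

  expect_error(pls1(X, rep(1, nrow(X))), "zero-variance")
  expect_error(pls1(X, y[-1]), "differ")
})

test_that("pls_permutation_p: self-association significant, determinism, guards", {
  set.seed(5)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- pls1(X, rnorm(40))$scores  # a direction X can explain perfectly
  p1 <- pls_permutation_p(X, y, n_perm = 200, mode = "shuffle", seed = 9)
  expect_lte(p1, 0.01)
  expect_identical(p1, pls_permutation_p(X, y, n_perm = 200,
                                         mode = "shuffle", seed = 9))
  expect_error(pls_permutation_p(X, y, n_perm = 50, mode = "shuffle"),
               ">= 100")
})

test_that("spin permutations are value-preserving bijections; identity map is maximally significant", {
  left <- left_fixture(40)
  cent <- parcellation_centroids(left)
  perms <- msnsubtype:::spin_permutations(cent, 25, seed = 3)
  for (i in 1:25) expect_setequal(perms[, i], seq_len(nrow(cent)))

  set.seed(6)
  m <- left$z + rnorm(nrow(left), 0, 0.1)
  st <- spin_test(m, m, cent, n_rot = 199, seed = 4)
  expect_equal(st$rho, 1)
  expect_equal(st$p_spin, 1 / 200)
  expect_error(spin_test(m, rep(1, length(m)), cent, 199), "constant")
})

test_that("bootstrap_gene_z separates a planted gradient gene from noise genes", {
  left <- left_fixture(50, seed = 7)
  target <- left$z
  sim <- simulate_expression(left, target, n_genes = 40, frac_pos = 0.05,
                             frac_neg = 0, noise_sd = 0.15, seed = 8)
  planted <- names(sim$truth)[sim$truth != 0]
  zt <- bootstrap_gene_z(sim$expr, target, B = 300, seed = 9)
  z <- setNames(zt$z, zt$gene)
  expect_true(all(z[planted] > 5))
  null_genes <- setdiff(names(z), planted)
  expect_gte(mean(abs(z[null_genes]) < 5), 0.9)

  # sign convention: negating the response negates Z
  zt_neg <- bootstrap_gene_z(sim$expr, -target, B = 300, seed = 9)
  expect_equal(setNames(zt_neg$z, zt_neg$gene)[names(z)], -z,
               tolerance = 1e-8)
  expect_error(bootstrap_gene_z(sim$expr[1:5, ], target[1:5], B = 50),
               ">= 10")
})

test_that("threshold_gene_lists applies strict Z cutoffs", {
  z <- c(g1 = 6.1, g2 = -5.2, g3 = 0.3, g4 = 5, g5 = -5, g6 = 8)
  lists <- threshold_gene_lists(z)
  expect_equal(lists$pos, c("g6", "g1"))   # sorted by |Z| descending
  expect_equal(lists$neg, "g2")
  expect_equal(threshold_gene_lists(c(a = 0.1, b = -0.2)),
               list(pos = character(0), neg = character(0)))
})

test_that("ish_gene_screen recovers planted genes with correct signs", {
  left <- left_fixture(50, seed = 10)
  target <- left$z
  sim <- simulate_expression(left, target, n_genes = 60, frac_pos = 0.1,
                             frac_neg = 0.1, noise_sd = 0.2, seed = 11)
  planted_pos <- names(sim$truth)[sim$truth > 0]
  planted_neg <- names(sim$truth)[sim$truth < 0]
  gene_list <- c(planted_pos, planted_neg,
                 sample(names(sim$truth)[sim$truth == 0], 10))
  cent <- parcellation_centroids(left)
  res <- ish_gene_screen(sim$expr, target, gene_list, cent, n_rot = 199,
                         seed = 12)
  expect_true(all(res$rho[res$gene %in% planted_pos] > 0.35))
  expect_true(all(res$rho[res$gene %in% planted_neg] < -0.35))
  expect_true(all(res$significant[res$gene %in% planted_pos]))

  # monotone transform of the t-map itself: rho = 1 and significant
  mono <- exp(target)
  sim2 <- sim$expr
  sim2[, 1] <- mono
  res2 <- ish_gene_screen(sim2, target, colnames(sim2)[1], cent,
                          n_rot = 199, seed = 13)
  expect_equal(res2$rho, 1)
  expect_true(res2$significant)

  expect_error(ish_gene_screen(sim$expr, target, c("nope"), cent, 199),
               "overlap")
})

test_that("dge_weight_correlation: exact at zero noise, flags small overlaps", {
  set.seed(14)
  genes <- sprintf("G%03d", 1:200)
  bg_w <- setNames(rnorm(200), genes)
  lst <- genes[1:40]
  dge <- data.frame(gene = genes[1:40],
                    log2fc = 2 * bg_w[1:40])
  dge$log2fc <- abs(dge$log2fc)  # all upregulated
  dge$log2fc <- 2 * abs(bg_w[1:40])
  # weights and log2fc perfectly monotone on the overlap
  w_lst <- abs(bg_w[lst]) / 2
  res <- dge_weight_correlation(w_lst, dge, bg_w, n_perm = 200, seed = 15)
  expect_equal(res$rho, 1)
  expect_equal(res$n_overlap, 40)
  expect_false(res$insufficient_overlap)

  small <- dge_weight_correlation(w_lst[1:3],
                                  dge[1:3, ], bg_w, n_perm = 200)
  expect_true(small$insufficient_overlap)
  expect_true(is.na(small$p_perm))

  multi <- dge_weight_correlations(w_lst,
    list(A = dge, B = data.frame(gene = genes[150:190],
                                 log2fc = rnorm(41))),
    bg_w, n_perm = 200, seed = 16)
  expect_equal(nrow(multi), 2)
  expect_true(all(multi$q >= multi$p_perm, na.rm = TRUE))
})

test_that("permutation nulls are calibrated (shuffle-PLS and DGE)", {
  # p values under the null are approximately uniform: check type-I error
  set.seed(17)
  n_rep <- 60
  pv <- vapply(seq_len(n_rep), function(i) {
    X <- matrix(rnorm(25 * 15), 25, 15)
    pls_permutation_p(X, rnorm(25), n_perm = 120, mode = "shuffle",
                      seed = i)
  }, 0)
  t1 <- mean(pv <= 0.05)
  expect_lt(abs(t1 - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 1e-9)

  genes <- sprintf("G%03d", 1:150)
  bg_w <- setNames(rnorm(150), genes)
  pv2 <- vapply(seq_len(n_rep), function(i) {
    set.seed(1000 + i)
    dge <- data.frame(gene = sample(genes, 30), log2fc = abs(rnorm(30)))
    dge_weight_correlation(bg_w[dge$gene], dge, bg_w, n_perm = 120,
                           seed = i)$p_perm
  }, 0)
  expect_lt(abs(mean(pv2 <= 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / n_rep) + 1e-9)
})

test_that("bootstrap SE shrinks like 1/sqrt(R) on fixed-signal simulations", {
  ses <- sapply(c(50, 200), function(R) {
    p <- make_parcellation(2 * R, R, seed = 20)
    left <- p[p$hemisphere == "left", ]
    sim <- simulate_expression(left, left$z, n_genes = 30, frac_pos = 0.1,
                               frac_neg = 0.1, noise_sd = 0.5, seed = 21)
    zt <- bootstrap_gene_z(sim$expr, left$z, B = 200, seed = 22)
    median(zt$se)
  })
  ratio <- ses[1] / ses[2]
  expect_gt(ratio, sqrt(4) * 0.6)   # ~2 expected
  expect_lt(ratio, sqrt(4) * 1.7)
})

test_that("applying the same relabelling to both maps leaves rho unchanged", {
  set.seed(23)
  a <- rnorm(40); b <- rnorm(40)
  rho <- cor(a, b, method = "spearman")
  for (i in 1:5) {
    perm <- sample(40)
    expect_equal(cor(a[perm], b[perm], method = "spearman"), rho,
                 tolerance = 1e-12)
  }
})

test_that("bh_fdr matches a hand step-up evaluation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # hand evaluation: q_i = min over j >= i of p_(j) * n / j
  p <- c(0.001, 0.02, 0.03, 0.5, 0.7)
  n <- length(p)
  q_hand <- sapply(seq_len(n), function(i)
    min(sapply(i:n, function(j) min(1, sort(p)[j] * n / j))))
  expect_equal(sort(bh_fdr(p)), q_hand)
  expect_error(bh_fdr(c(0.5, 1.2)), "invalid")
})
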