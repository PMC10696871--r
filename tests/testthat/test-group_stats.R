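# group_stats: regional GLM, global test, quadrants, trajectories,
# symptom correlations, demographics.

make_meta <- function(n, group) {
  data.frame(subject_id = sprintf("S%02d", 1:n), group = group,
             age = runif(n, 8, 17), sex01 = rbinom(n, 1, 0.5),
             sex = "M", tiv = rnorm(n, 1465, 120))
}

test_that("fit_region_glm: identical groups give t = 0; contrast antisymmetry; Bonferroni", {
  set.seed(2)
  n <- 40
  meta <- make_meta(n, rep(c("control", "patient"), each = n / 2))
  base <- matrix(rnorm(n / 2 * 6), n / 2, 6)
  # identical strength vectors in both groups and identical covariates
  meta$age <- rep(meta$age[1:(n / 2)], 2)
  meta$sex01 <- rep(meta$sex01[1:(n / 2)], 2)
  meta$tiv <- rep(meta$tiv[1:(n / 2)], 2)
  S <- rbind(base, base)
  tm <- fit_region_glm(S, meta)
  expect_true(all(abs(tm$t) < 1e-8))
  expect_true(all(tm$p_bonf >= tm$p))
  expect_equal(tm$p_bonf, pmin(1, tm$p * 6))

  # antisymmetry: swapping case/control labels negates t
  set.seed(3)
  S2 <- matrix(rnorm(n * 6), n, 6)
  t_fwd <- fit_region_glm(S2, meta)$t
  meta_sw <- meta
  meta_sw$group <- ifelse(meta$group == "control", "patient", "control")
  t_rev <- fit_region_glm(S2, meta_sw)$t
  expect_equal(t_fwd, -t_rev, tolerance = 1e-10)

  # shifting age by a constant leaves the group t untouched
  meta_shift <- meta; meta_shift$age <- meta$age + 100
  expect_equal(fit_region_glm(S2, meta_shift)$t, t_fwd, tolerance = 1e-8)

  # rank deficiency is reported
  meta_bad <- meta; meta_bad$tiv <- 1500
  expect_error(fit_region_glm(S2, meta_bad), "rank-deficient")
})

test_that("fit_region_glm agrees with lm() per region", {
  set.seed(4)
  n <- 36
  meta <- make_meta(n, sample(rep(c("control", "patient"), each = n / 2)))
  S <- matrix(rnorm(n * 4), n, 4)
  tm <- fit_region_glm(S, meta)
  for (r in 1:4) {
    fit <- lm(S[, r] ~ I(meta$group == "patient") + meta$age + meta$sex01 +
                meta$tiv)
    sm <- summary(fit)$coefficients[2, ]
    expect_equal(tm$beta[r], unname(sm["Estimate"]), tolerance = 1e-10)
    expect_equal(tm$t[r], unname(sm["t value"]), tolerance = 1e-10)
    expect_equal(tm$p[r], unname(sm["Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("planted effects are recovered with correct signs; global test responds", {
  sc <- small_cohort(n_control = 50, n_patient = 50)
  S <- cohort_strengths(sc$cohort$features)
  m1 <- subtype_contrast_meta(sc$cohort$meta,
    stats::setNames(sc$cohort$meta$subtype_truth[sc$cohort$meta$group == "patient"],
                    sc$cohort$meta$subject_id[sc$cohort$meta$group == "patient"]), 1)
  tm <- fit_region_glm(S[match(m1$subject_id, rownames(S)), ], m1,
                       case_level = "case")
  aff <- sc$config$subtypes[[1]]
  eff <- rep_len(aff$effect, length(aff$regions))
  t_aff <- tm$t[aff$regions]
  expect_gt(mean(sign(t_aff) == sign(eff)), 0.9)

  # a planted reduction over most of the cortex yields a negative global t
  # (a perfectly uniform shift would be absorbed by the per-subject
  # z-normalization, so the effect is planted on a 2/3 majority of regions)
  p <- sc$parcellation
  many <- p$region_id[seq_len(round(nrow(p) * 2 / 3))]
  cfg_dn <- list(proportions = 1,
                 subtypes = list(list(regions = many, effect = -2)))
  coh <- simulate_cohort(p, 40, 40, cfg_dn, seed = 10)
  Sg <- cohort_strengths(coh$features)
  g <- global_strength_test(Sg, coh$meta)
  expect_lt(g$t, 0)
  expect_lt(g$p, 0.05)
})

test_that("quadrant_fractions counts quadrants exactly", {
  qf <- quadrant_fractions(c(1, 1, -1, -1), c(-1, 1, 1, -1))
  expect_equal(unname(qf), rep(0.25, 4))

  # t = -strength puts every nonzero region in an opposite-sign quadrant
  s <- c(2, 1, -3, -1, 4)
  qf2 <- quadrant_fractions(s, -s)
  expect_equal(unname(qf2["decoupling"] + qf2["dedifferentiation"]), 1)
  expect_equal(unname(qf2["hypercoupling"]), 0)
  expect_equal(unname(qf2["hyperdifferentiation"]), 0)

  set.seed(6)
  a <- rnorm(100); b <- rnorm(100)
  qf3 <- quadrant_fractions(a, b)
  brute <- c(0, 0, 0, 0)
  for (i in 1:100) {
    if (a[i] > 0 && b[i] < 0) brute[1] <- brute[1] + 1
    if (a[i] < 0 && b[i] > 0) brute[2] <- brute[2] + 1
    if (a[i] > 0 && b[i] > 0) brute[3] <- brute[3] + 1
    if (a[i] < 0 && b[i] < 0) brute[4] <- brute[4] + 1
  }
  expect_equal(unname(qf3), brute / 100)
  expect_lte(sum(qf3), 1)
  expect_error(quadrant_fractions(a, b[-1]), "mismatch")
})

test_that("fit_quadratic_trajectory recovers exact and noisy quadratics", {
  age <- seq(7, 17, length.out = 50)
  # exact fits trigger lm's "essentially perfect fit" warning, expected here
  cfit <- suppressWarnings(fit_quadratic_trajectory(age, rep(2, 50)))
  expect_equal(unname(cfit$coefficients), c(2, 0, 0), tolerance = 1e-10)
  qfit <- suppressWarnings(fit_quadratic_trajectory(age, age^2))
  expect_equal(unname(qfit$coefficients), c(0, 0, 1), tolerance = 1e-8)
  expect_equal(qfit$predict(10), 100, tolerance = 1e-8)

  set.seed(7)
  n <- 100
  a <- runif(n, 7, 17)
  y <- 1 + 0.5 * a - 0.03 * a^2 + rnorm(n, 0, 0.2)
  nf <- fit_quadratic_trajectory(a, y)
  expect_true(all(abs(nf$coefficients - c(1, 0.5, -0.03)) < 3 * nf$se))
  expect_error(fit_quadratic_trajectory(c(1, 1, 2), c(1, 2, 3)), "distinct")
})

test_that("symptom_spearman handles perfect, null, and tied data", {
  set.seed(8)
  n <- 30
  S <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("r1", "r2", "r3")))
  scores <- data.frame(total = rank(S[, 1]))  # perfect rank agreement
  res <- symptom_spearman(S, scores)
  expect_equal(res$rho[res$region == "r1"], 1)

  # independent scores: essentially no Bonferroni survivors
  scores2 <- data.frame(a = rnorm(n), b = rnorm(n))
  res2 <- symptom_spearman(S, scores2)
  expect_true(all(res2$p_bonf > 0.05))

  # ties handled as average ranks: agree with cor(method = "spearman")
  x <- c(1, 2, 2, 3, 3, 3, 4, 5, 6, 7)
  y <- c(2, 1, 3, 3, 5, 4, 4, 6, 7, 7)
  res3 <- symptom_spearman(matrix(x, ncol = 1, dimnames = list(NULL, "r")),
                           data.frame(s = y))
  expect_equal(res3$rho, cor(x, y, method = "spearman"))

  expect_error(symptom_spearman(S, data.frame(c = rep(1, n))), "constant")
  expect_error(symptom_spearman(S[1:3, ], data.frame(s = 1:3)), ">= 4")
})

test_that("demographics_tests covers U tests and chi-square", {
  set.seed(9)
  meta <- data.frame(group = rep(c("a", "b"), each = 50),
                     age = c(rnorm(50, 14, 2), rnorm(50, 14, 2)),
                     sex = rep(rep(c("M", "F"), c(30, 20)), 2),
                     tiv = rnorm(100, 1465, 100))
  res <- demographics_tests(meta)
  expect_setequal(res$variable, c("age", "tiv", "sex"))
  # balanced 2x2 table -> chi-square statistic 0
  expect_equal(res$statistic[res$variable == "sex"], 0, tolerance = 1e-12)

  # identical samples: p in the upper tail of the U distribution
  meta_id <- meta
  meta_id$age <- rep(meta$age[1:50], 2)
  res_id <- demographics_tests(meta_id, continuous = "age")
  expect_gte(res_id$p[res_id$variable == "age"], 0.99)

  # strongly shifted distributions are detected
  meta_sh <- meta
  meta_sh$age[meta_sh$group == "b"] <- meta_sh$age[meta_sh$group == "b"] + 5
  res_sh <- demographics_tests(meta_sh, continuous = "age")
  expect_lt(res_sh$p[res_sh$variable == "age"], 0.01)

  expect_error(demographics_tests(meta[meta$group == "a", ]), "two groups")
})
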