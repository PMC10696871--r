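# Case-control regional statistics, global tests, quadrant fractions,
# developmental trajectories, symptom correlations, and demographics tests.

#' Region-wise case-control linear model
#'
#' Per region, ordinary least squares of MSN strength on
#' `[intercept, group, age, sex, TIV]`; the reported t and two-sided p belong
#' to the group indicator (case = 1, control = 0), so positive t means higher
#' strength in cases. Bonferroni correction is applied across regions.
#'
#' @param strengths subject x region matrix.
#' @param meta metadata with columns `group`, `age`, `sex01`, `tiv`.
#' @param case_level,control_level labels selecting the contrast; subjects
#'   with other labels are dropped. For subtype contrasts pass a metadata
#'   table whose `group` column encodes the subtype (see
#'   [subtype_contrast_meta()]).
#' @return a `data.frame` of class `tstat_map` with columns `region`, `beta`,
#'   `t`, `p`, `p_bonf`; covariate coefficient estimates are kept in
#'   `attr(, "covariates")`, the contrast in `attr(, "contrast")`.
#' @export
fit_region_glm <- function(strengths, meta, case_level = "patient",
                           control_level = "control") {
  strengths <- as.matrix(strengths)
  stopifnot(nrow(strengths) == nrow(meta))
  keep <- meta$group %in% c(case_level, control_level)
  if (!any(meta$group == case_level) || !any(meta$group == control_level))
    stop("both contrast groups must be present")
  Y <- strengths[keep, , drop = FALSE]
  m <- meta[keep, , drop = FALSE]
  D <- cbind(intercept = 1, group = as.numeric(m$group == case_level),
             age = m$age, sex = m$sex01, tiv = m$tiv)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[seq(qrD$rank + 1, ncol(D))]]
    stop("rank-deficient design (collinear covariates): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrD, Y)
  res <- Y - D %*% beta
  df <- nrow(D) - ncol(D)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrD))
  se_group <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- beta["group", ] / se_group
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  out <- data.frame(
    region = colnames(strengths) %||% as.character(seq_len(ncol(strengths))),
    beta = beta["group", ], t = tval, p = p,
    p_bonf = pmin(1, p * ncol(Y)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "covariates") <- beta[c("intercept", "age", "sex", "tiv"), , drop = FALSE]
  attr(out, "contrast") <- paste0(case_level, "-", control_level)
  attr(out, "df") <- df
  class(out) <- c("tstat_map", "data.frame")
  out
}

#' Metadata recoded for a subtype-vs-control contrast
#'
#' Relabels patients of the chosen planted/estimated subtype as the case
#' group and drops the other patients, so [fit_region_glm()] and
#' [global_strength_test()] can run a subtype-vs-HC contrast directly.
#'
#' @param meta cohort metadata.
#' @param assignments named vector of subtype labels over patients
#'   (names = subject ids), e.g. from [hydra_fit()].
#' @param k subtype to treat as cases.
#' @return metadata with `group` recoded to `"case"` / `"control"`.
#' @export
subtype_contrast_meta <- function(meta, assignments, k) {
  m <- meta
  sub <- assignments[match(m$subject_id, names(assignments))]
  m$group <- ifelse(m$group == "control", "control",
                    ifelse(!is.na(sub) & sub == k, "case", NA))
  m[!is.na(m$group), , drop = FALSE]
}

#' Global strength case-control test
#'
#' The same covariate-adjusted linear model as [fit_region_glm()], applied to
#' the per-subject global strength (mean over regions).
#'
#' @inheritParams fit_region_glm
#' @return one-row data.frame with `beta`, `t`, `p`.
#' @export
global_strength_test <- function(strengths, meta, case_level = "patient",
                                 control_level = "control") {
  g <- matrix(rowMeans(as.matrix(strengths)), ncol = 1,
              dimnames = list(NULL, "global"))
  res <- fit_region_glm(g, meta, case_level, control_level)
  data.frame(beta = res$beta, t = res$t, p = res$p)
}

#' Quadrant fractions of a strength map against a t-map
#'
#' Classifies regions by the sign of the reference (control) strength versus
#' the sign of the case-control t: decoupling (strength > 0, t < 0),
#' dedifferentiation (strength < 0, t > 0), hypercoupling (both > 0),
#' hyperdifferentiation (both < 0). Fractions are of all regions; exact
#' zeros fall in no quadrant, so the four fractions sum to at most 1.
#'
#' @param hc_strength reference strength map (vector over regions).
#' @param tmap t values over the same regions.
#' @return named numeric vector of the four fractions.
#' @export
quadrant_fractions <- function(hc_strength, tmap) {
  if (length(hc_strength) != length(tmap)) stop("length mismatch")
  R <- length(tmap)
  c(decoupling = sum(hc_strength > 0 & tmap < 0) / R,
    dedifferentiation = sum(hc_strength < 0 & tmap > 0) / R,
    hypercoupling = sum(hc_strength > 0 & tmap > 0) / R,
    hyperdifferentiation = sum(hc_strength < 0 & tmap < 0) / R)
}

#' Quadratic developmental trajectory fit
#'
#' Least-squares fit of `value = b0 + b1 age + b2 age^2`, the standard
#' low-order model for non-linear age effects on brain measures.
#'
#' @param age,values numeric vectors.
#' @return list with `coefficients` (b0, b1, b2), `r_squared`, and
#'   `predict(age)`.
#' @export
fit_quadratic_trajectory <- function(age, values) {
  if (length(unique(age)) < 3) stop("need >= 3 distinct ages")
  fit <- stats::lm(values ~ age + I(age^2))
  b <- unname(stats::coef(fit))
  list(coefficients = c(b0 = b[1], b1 = b[2], b2 = b[3]),
       r_squared = summary(fit)$r.squared,
       se = unname(summary(fit)$coefficients[, "Std. Error"]),
       predict = function(a) b[1] + b[2] * a + b[3] * a^2)
}

#' Symptom-strength Spearman correlations
#'
#' Spearman rank correlation of each region's strength with each symptom
#' score across patients; ties handled as average ranks. The p values use
#' the t approximation, with Bonferroni correction over the full
#' region x score grid.
#'
#' @param strengths patient x region matrix.
#' @param scores patient x score data.frame or matrix (e.g. PANSS subscales).
#' @return data.frame with `region`, `score`, `rho`, `p`, `p_bonf`.
#' @export
symptom_spearman <- function(strengths, scores) {
  strengths <- as.matrix(strengths)
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(strengths)) stop("row mismatch")
  if (nrow(scores) < 4) stop("need >= 4 patients with scores")
  const <- apply(scores, 2, function(s) stats::sd(s, na.rm = TRUE) == 0)
  if (any(const)) stop("constant score vector: ",
                       paste(colnames(scores)[const], collapse = ", "))
  grid <- expand.grid(region = colnames(strengths) %||% seq_len(ncol(strengths)),
                      score = colnames(scores) %||% seq_len(ncol(scores)),
                      stringsAsFactors = FALSE)
  est <- mapply(function(r, s) {
    x <- strengths[, r]; y <- scores[, s]
    ok <- stats::complete.cases(x, y)
    rho <- stats::cor(x[ok], y[ok], method = "spearman")
    n <- sum(ok)
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    c(rho = rho, p = if (is.nan(p)) 0 else p)
  }, grid$region, grid$score)
  out <- cbind(grid, t(est))
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out
}

#' Demographic group-difference tests
#'
#' Two-sided Mann-Whitney U tests for continuous variables and a chi-square
#' test (without continuity correction) for sex, comparing two groups as in
#' standard cohort characteristics tables.
#'
#' @param meta metadata with `group`, `sex`, and the continuous columns.
#' @param group_col grouping column (default `"group"`).
#' @param continuous columns to test with Mann-Whitney (defaults to those of
#'   `age`, `tiv`, `panss_*` that are present).
#' @return data.frame with `variable`, `test`, `statistic`, `p`.
#' @export
demographics_tests <- function(meta, group_col = "group",
                               continuous = NULL) {
  g <- meta[[group_col]]
  lev <- unique(g)
  if (length(lev) != 2) stop("need exactly two groups")
  if (any(table(g) == 0)) stop("empty group")
  if (is.null(continuous))
    continuous <- intersect(c("age", "tiv", "panss_total", "panss_positive",
                              "panss_negative", "panss_general"), names(meta))
  rows <- lapply(continuous, function(v) {
    x <- meta[[v]][g == lev[1]]; y <- meta[[v]][g == lev[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) return(NULL)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(variable = v, test = "mann-whitney",
               statistic = unname(wt$statistic), p = wt$p.value)
  })
  if ("sex" %in% names(meta)) {
    tab <- table(g, meta$sex)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows <- c(rows, list(data.frame(variable = "sex", test = "chi-square",
                                    statistic = unname(ct$statistic),
                                    p = ct$p.value)))
  }
  do.call(rbind, rows)
}
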