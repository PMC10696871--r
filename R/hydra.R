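# HYDRA: heterogeneity through discriminant analysis.
#
# Semi-supervised max-margin clustering: K linear classifiers (polytope faces)
# jointly separate controls from patients; each patient is assigned to the
# face giving it the largest margin, and the face memberships define the
# subtypes. The objective minimized is
#
#   sum_j [ 1/2 ||w_j||^2
#           + C * sum_{controls} (1/K) * hinge(1 + w_j'x + b_j)
#           + C * sum_{patients} s_ij * hinge(1 - w_j'x - b_j) ]
#
# with s_ij in {0,1}, sum_j s_ij = 1, by block-coordinate descent alternating
# (a) a weighted soft-margin linear classifier fit per face given the
# assignments and (b) reassignment of each patient to its best face. Both
# steps are monotone, so the objective trace is non-increasing. Multiple
# seeded initializations are combined through a co-assignment consensus
# matrix clustered by average linkage.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: `(sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)` and
#' `M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. Returns 1 for identical
#' partitions up to relabelling; approximately 0 for independent partitions.
#'
#' @param a,b label vectors of equal length (any comparable type).
#' @return scalar ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 items")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  e <- sum_a * sum_b / choose2(n)
  m <- (sum_a + sum_b) / 2
  if (m == e) return(ifelse(sum_ij == e, 1, 0))  # degenerate: all singletons / one block
  (sum_ij - e) / (m - e)
}

# Weighted soft-margin linear classifier, primal form:
#   min 1/2 ||w||^2 + sum_i c_i * hinge(1 - y_i (w'x_i + b))
# solved by L-BFGS-B on a Huber-smoothed hinge (delta = 1e-4), warm-started.
# Returns list(w, b, value).
svm_weighted <- function(X, y, cw, init = NULL, delta = 1e-4, maxit = 300L) {
  d <- ncol(X)
  keep <- cw > 0
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]
  ck <- cw[keep]
  # fn and gr share the margin computation; L-BFGS-B evaluates both at the
  # same point, so cache the last linear predictor
  cache <- new.env(parent = emptyenv())
  margins <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$z)
    z <- 1 - yk * (drop(Xk %*% par[seq_len(d)]) + par[d + 1])
    cache$par <- par; cache$z <- z
    z
  }
  fn <- function(par) {
    z <- margins(par)
    q <- pmax(z, 0)
    h <- q - delta / 2
    sm <- q < delta
    h[sm] <- q[sm]^2 / (2 * delta)
    0.5 * sum(par[seq_len(d)]^2) + sum(ck * h)
  }
  gr <- function(par) {
    z <- margins(par)
    dh <- pmin(pmax(z / delta, 0), 1)
    g <- ck * dh * yk
    c(par[seq_len(d)] - drop(crossprod(Xk, g)), -sum(g))
  }
  par0 <- init %||% numeric(d + 1)
  res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e6))
  list(w = res$par[seq_len(d)], b = res$par[d + 1], value = res$value)
}

# Production solver for the same weighted soft-margin problem: exact dual
# coordinate descent in compiled code, intercept via an augmented constant
# feature of value `bias_scale` (penalized intercept, as in liblinear /
# LinearSVC; the penalty (b/bias_scale)^2/2 is negligible at the default
# scale). `value` reports the objective the solver actually minimizes --
# including the intercept penalty -- so the alternating-optimization trace
# is genuinely non-increasing. svm_weighted() above is kept as an
# independent pure-R reference implementation for the test suite.
svm_weighted_cd <- function(X, y, cw, bias_scale = 10, tol = 1e-4,
                            max_pass = 300L, seed = 1L) {
  keep <- which(cw > 0)
  Xt <- rbind(t(X[keep, , drop = FALSE]), bias_scale)
  fit <- svm_cd(Xt, y[keep], cw[keep], max_pass = max_pass, tol = tol,
                seed = as.integer(seed))
  d <- ncol(X)
  w <- fit$v[seq_len(d)]
  b <- bias_scale * fit$v[d + 1]
  margins <- 1 - y * (drop(X %*% w) + b)
  value <- 0.5 * sum(w^2) + 0.5 * (b / bias_scale)^2 +
    sum(cw * pmax(margins, 0))
  list(w = w, b = b, value = value)
}

# One seeded HYDRA run: k-means++-style initialization of the patient
# assignments (on a spectrally denoised projection of the patient rows, see
# hydra_fit), then alternating optimization. Returns assignments, faces and
# the (smoothed-hinge) objective trace.
hydra_run <- function(X, is_patient, K, C, n_iter, seed, init_rows = NULL) {
  n <- nrow(X); d <- ncol(X)
  pat_idx <- which(is_patient)
  ctl_idx <- which(!is_patient)
  y <- ifelse(is_patient, 1, -1)

  P0 <- init_rows %||% X[pat_idx, , drop = FALSE]
  assign_vec <- with_seed(seed, kmeanspp_assign(P0, K))
  faces <- replicate(K, NULL, simplify = FALSE)
  trace <- numeric(0)
  repairs <- integer(0)   # empty-face reseeds per alternation (break descent)
  prev_assign <- rep(-1L, length(pat_idx))
  best_obj <- Inf
  stall <- 0L             # iterations without objective improvement

  for (it in seq_len(n_iter)) {
    # (a) face estimation given assignments
    obj <- 0
    for (j in seq_len(K)) {
      cw <- numeric(n)
      cw[ctl_idx] <- C / K
      cw[pat_idx[assign_vec == j]] <- C
      faces[[j]] <- svm_weighted_cd(X, y, cw,
                                    seed = child_seed(seed, it * 100L + j))
      obj <- obj + faces[[j]]$value
    }
    trace <- c(trace, obj)
    # (b) reassignment. Any face with raw margin >= 1 gives that patient zero
    # hinge loss, so the objective only determines the assignment up to ties;
    # among hinge-minimizing faces we break ties by the largest geometric
    # (norm-normalized) signed distance, which keeps the descent exact while
    # avoiding the degenerate attraction toward large-norm faces.
    M <- vapply(faces, function(f) drop(X[pat_idx, , drop = FALSE] %*% f$w) + f$b,
                numeric(length(pat_idx)))
    M <- matrix(M, ncol = K)
    wn <- vapply(faces, function(f) max(sqrt(sum(f$w^2)), 1e-12), 0)
    H <- pmax(1 - M, 0)                       # hinge loss per face
    Dst <- sweep(M, 2, wn, "/")               # geometric signed distance
    assign_vec <- vapply(seq_len(nrow(M)), function(i) {
      cand <- which(H[i, ] <= min(H[i, ]) + 1e-9)
      cand[which.max(Dst[i, cand])]
    }, 0L)
    # repair empty faces with the worst-margin patient
    n_rep <- 0L
    for (j in seq_len(K)) {
      if (!any(assign_vec == j)) {
        worst <- which.min(apply(M, 1, max))
        assign_vec[worst] <- j
        M[worst, ] <- -Inf  # cannot be stolen again this round
        n_rep <- n_rep + 1L
      }
    }
    repairs <- c(repairs, n_rep)
    if (identical(assign_vec, prev_assign)) break
    # repair-induced cycles can keep assignments churning; stop once the
    # objective has plateaued (n_iter remains the hard cap)
    if (obj < best_obj - 1e-8) {
      best_obj <- obj
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 3L) break
    }
    prev_assign <- assign_vec
  }
  list(assignments = assign_vec, faces = faces, trace = trace,
       repairs = repairs)
}

# k-means++ seeding followed by a single nearest-centre assignment.
kmeanspp_assign <- function(P, K) {
  n <- nrow(P)
  if (K >= n) return(seq_len(max(1, n)) %% K + 1L)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(P, 2, P[centers[1], ], "-")^2)
  if (K > 1) for (j in 2:K) {
    probs <- d2 / sum(d2)
    if (!all(is.finite(probs)) || sum(d2) == 0) probs <- rep(1 / n, n)
    centers[j] <- sample.int(n, 1, prob = probs)
    d2 <- pmin(d2, rowSums(sweep(P, 2, P[centers[j], ], "-")^2))
  }
  cent <- P[centers, , drop = FALSE]
  dists <- vapply(seq_len(K), function(j)
    rowSums(sweep(P, 2, cent[j, ], "-")^2), numeric(n))
  max.col(-matrix(dists, ncol = K), ties.method = "first")
}

#' Fit the HYDRA polytope model
#'
#' Runs `n_consensus` seeded alternating-optimization runs (50 alternations
#' each by default, regularization `C = 0.25`), accumulates a patient x
#' patient co-assignment consensus matrix, and derives the final subtype
#' assignment by average-linkage agglomerative clustering of
#' `1 - co-assignment frequency` into `K` groups. `K = 1` reduces to a single
#' weighted linear max-margin classifier.
#'
#' @param X subject x feature matrix (patients and controls).
#' @param y group labels; values equal to `patient_level` are patients.
#' @param K number of polytope faces (subtypes).
#' @param C regularization parameter (default 0.25).
#' @param n_iter maximum alternations per run (default 50; runs stop early
#'   when assignments stabilize, which block-coordinate descent guarantees
#'   to be a fixed point).
#' @param n_consensus number of seeded initializations (default 20).
#' @param seed integer seed.
#' @param standardize z-score feature columns first (default TRUE).
#' @param patient_level label value marking patients (default `"patient"`).
#' @return object of class `hydra_fit`: `assignments` (named integer vector
#'   over patients), `consensus` (co-assignment matrix), `hyperplanes` (list
#'   of `w`, `b` per face, refit on the consensus assignment),
#'   `objective_traces` (one numeric vector per consensus run), `K`.
#' @export
hydra_fit <- function(X, y, K, C = 0.25, n_iter = 50L, n_consensus = 20L,
                      seed = 1L, standardize = TRUE,
                      patient_level = "patient") {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  is_patient <- y == patient_level
  if (!any(is_patient) || all(is_patient)) stop("both classes must be present")
  n_pat <- sum(is_patient)
  if (K < 1) stop("K must be >= 1")
  if (K > n_pat) stop("K exceeds the number of patients")
  if (standardize) X <- zscore_cols(X)

  pat_ids <- rownames(X)[is_patient] %||% as.character(which(is_patient))

  # initialization space: patients' deviation directions from the control
  # cloud, whitened by the (shrunk) control covariance and length-normalized.
  # Whitening downweights variance directions the controls share (e.g. a
  # global strength factor), and normalization leaves only the direction of
  # departure -- the quantity HYDRA's polytope faces discriminate on. Raw
  # high-dimensional rows would make k-means++ seeds noise-driven. Only used
  # to seed the assignments; the optimization itself is untouched.
  ctl_rows <- X[!is_patient, , drop = FALSE]
  dev <- sweep(X[is_patient, , drop = FALSE], 2, colMeans(ctl_rows))
  init_rows <- dev
  if (nrow(ctl_rows) >= 3) {
    cv <- stats::cov(ctl_rows)
    lam <- 0.2 * mean(diag(cv))
    ei <- eigen(cv + lam * diag(ncol(X)), symmetric = TRUE)
    init_rows <- dev %*% (ei$vectors %*% (t(ei$vectors) / sqrt(ei$values)))
  }
  nrm <- sqrt(rowSums(init_rows^2))
  init_rows <- init_rows / pmax(nrm, 1e-12)

  co <- matrix(0, n_pat, n_pat, dimnames = list(pat_ids, pat_ids))
  traces <- vector("list", n_consensus)
  repair_log <- vector("list", n_consensus)
  for (r in seq_len(n_consensus)) {
    run <- hydra_run(X, is_patient, K, C, n_iter, seed = child_seed(seed, r),
                     init_rows = init_rows)
    traces[[r]] <- run$trace
    repair_log[[r]] <- run$repairs
    co <- co + outer(run$assignments, run$assignments, "==")
  }
  co <- co / n_consensus

  if (K == 1L) {
    assignments <- rep(1L, n_pat)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
    assignments <- stats::cutree(hc, k = K)
    # deterministic labelling: clusters numbered by their lowest patient index
    first <- vapply(seq_len(K), function(k) min(which(assignments == k)), 0L)
    assignments <- order(order(first))[assignments]
  }
  names(assignments) <- pat_ids

  # refit faces once on the consensus assignment so the returned hyperplanes
  # describe the reported subtypes
  y_pm <- ifelse(is_patient, 1, -1)
  faces <- lapply(seq_len(K), function(j) {
    cw <- numeric(nrow(X))
    cw[!is_patient] <- C / K
    cw[which(is_patient)[assignments == j]] <- C
    f <- svm_weighted_cd(X, y_pm, cw, seed = child_seed(seed, 999L + j))
    list(w = f$w, b = f$b)
  })

  structure(list(assignments = assignments, consensus = co,
                 hyperplanes = faces, objective_traces = traces,
                 repairs = repair_log, K = K, C = C),
            class = "hydra_fit")
}

#' Cross-validated cluster-stability scan over K
#'
#' For each candidate `K`, HYDRA is fit on each of the `folds`
#' leave-one-fold-out training sets; stability is the mean pairwise adjusted
#' Rand index between the `choose(folds, 2)` run pairs, computed on the
#' patients common to both training sets. The selected model order is the
#' `K` maximizing mean stability (ties broken toward smaller `K`).
#'
#' @param X subject x feature matrix.
#' @param y group labels (see [hydra_fit()]).
#' @param k_range candidate cluster counts (default `2:10`).
#' @param folds number of cross-validation folds (default 10, stratified by
#'   group).
#' @param seed integer seed (fold split and HYDRA initializations).
#' @param ... further arguments passed to [hydra_fit()] (e.g. `C`,
#'   `n_consensus`, `n_iter`).
#' @return object of class `cv_ari`: data.frame `table` with columns `k`,
#'   `ari`; `chosen_k`; `fold_assignments` (per K, per fold).
#' @export
cv_ari <- function(X, y, k_range = 2:10, folds = 10L, seed = 1L, ...) {
  X <- as.matrix(X)
  if (length(k_range) == 0) stop("k_range is empty")
  groups <- unique(y)
  if (min(table(y)) < folds) stop("need at least `folds` subjects per class")
  n <- nrow(X)
  fold_id <- integer(n)
  with_seed(seed, {
    for (g in groups) {
      idx <- which(y == g)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })

  ids <- rownames(X) %||% as.character(seq_len(n))
  rownames(X) <- ids
  mean_ari <- numeric(length(k_range))
  all_assign <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    fits <- lapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      hydra_fit(X[tr, , drop = FALSE], y[tr], K = K,
                seed = child_seed(seed, K * 1000L + f), ...)$assignments
    })
    pairs <- utils::combn(folds, 2)
    aris <- apply(pairs, 2, function(p) {
      common <- intersect(names(fits[[p[1]]]), names(fits[[p[2]]]))
      if (length(common) < 2) return(NA_real_)
      adjusted_rand_index(fits[[p[1]]][common], fits[[p[2]]][common])
    })
    mean_ari[ki] <- mean(aris, na.rm = TRUE)
    all_assign[[ki]] <- fits
  }
  tab <- data.frame(k = k_range, ari = mean_ari)
  chosen <- k_range[which.max(mean_ari)]  # which.max takes first max: ties -> smaller K
  structure(list(table = tab, chosen_k = chosen,
                 fold_assignments = stats::setNames(all_assign, k_range)),
            class = "cv_ari")
}

#' Residualize strengths on covariates estimated in controls
#'
#' Fits `strength ~ age + sex + TIV` per region on controls only and removes
#' the fitted covariate effect from every subject, so subtyping operates on
#' covariate-adjusted deviations (consistent with the case-control linear
#' model used later).
#'
#' @param strengths subject x region matrix.
#' @param meta metadata with `age`, `sex01`, `tiv`, `group`.
#' @param control_level label of the reference group (default `"control"`).
#' @return residualized subject x region matrix.
#' @export
residualize_strengths <- function(strengths, meta, control_level = "control") {
  strengths <- as.matrix(strengths)
  stopifnot(nrow(strengths) == nrow(meta))
  D <- cbind(1, meta$age, meta$sex01, meta$tiv)
  ctl <- meta$group == control_level
  if (sum(ctl) < ncol(D)) stop("too few controls to fit covariates")
  beta <- qr.coef(qr(D[ctl, , drop = FALSE]), strengths[ctl, , drop = FALSE])
  strengths - D %*% beta
}

#' @export
print.hydra_fit <- function(x, ...) {
  cat("HYDRA fit: K =", x$K, ", C =", x$C, "\n")
  print(table(x$assignments))
  invisible(x)
}

#' @export
print.cv_ari <- function(x, ...) {
  cat("Cross-validated cluster stability (ARI):\n")
  print(x$table, row.names = FALSE)
  cat("chosen K =", x$chosen_k, "\n")
  invisible(x)
}
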