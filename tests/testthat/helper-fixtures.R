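# Shared fixtures, built in code. Small cohorts keep the default test run
# fast; acceptance-scale runs live in test-acceptance.R.

small_parcellation <- function(n = 40, n_left = 20, seed = 1) {
  make_parcellation(n, n_left, seed = seed)
}

# A compact cohort with strongly planted mirrored subtypes (reduced copy of
# the paper_default structure).
small_cohort <- function(n_control = 40, n_patient = 40, n_regions = 64,
                         effect = 2.5, noise_sd = 0.35, seed = 5) {
  p <- make_parcellation(n_regions, n_regions / 2, seed = 1)
  cfg <- paper_default_config(p, effect_magnitude = effect, n_affected = 12L)
  cfg$n_control <- n_control
  cfg$n_patient <- n_patient
  coh <- simulate_cohort(p, n_control, n_patient, cfg, noise_sd = noise_sd,
                         seed = seed)
  list(parcellation = p, config = cfg, cohort = coh)
}

# Independent two-pass Pearson correlation, used as the brute-force oracle
# against build_msn.
pearson_oracle <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Contingency-formula ARI oracle, written against the textbook formula with
# explicit loops (independent of adjusted_rand_index's vectorized path).
ari_oracle <- function(a, b) {
  ua <- unique(a); ub <- unique(b)
  n <- length(a)
  ch2 <- function(x) if (x < 2) 0 else x * (x - 1) / 2
  sum_ij <- 0
  for (i in ua) for (j in ub)
    sum_ij <- sum_ij + ch2(sum(a == i & b == j))
  sum_a <- 0; for (i in ua) sum_a <- sum_a + ch2(sum(a == i))
  sum_b <- 0; for (j in ub) sum_b <- sum_b + ch2(sum(b == j))
  e <- sum_a * sum_b / ch2(n)
  m <- (sum_a + sum_b) / 2
  if (m == e) return(if (abs(sum_ij - e) < 1e-12) 1 else 0)
  (sum_ij - e) / (m - e)
}

# Directly coded ssGSEA running-sum evaluation, independent of the
# vectorized path in ssgsea_region_scores.
ssgsea_oracle <- function(x, set_genes, alpha = 0.25) {
  genes <- names(x)
  G <- length(x)
  ord <- order(x, decreasing = TRUE)
  sorted_genes <- genes[ord]
  rnk_weight <- (G:1)^alpha           # weight of the i-th sorted position
  inset <- sorted_genes %in% set_genes
  w_in_total <- sum(rnk_weight[inset])
  n_out <- sum(!inset)
  p_in <- 0; p_out <- 0; score <- 0
  for (i in seq_len(G)) {
    if (inset[i]) p_in <- p_in + rnk_weight[i] / w_in_total
    else p_out <- p_out + 1 / n_out
    score <- score + (p_in - p_out)
  }
  score
}

# All set partitions of seq_len(n) into at most k blocks, as label vectors.
partitions_up_to_k <- function(n, k) {
  out <- list()
  recurse <- function(labels, next_item, max_used) {
    if (next_item > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(min(max_used + 1, k))) {
      labels[next_item] <- lab
      recurse(labels, next_item + 1, max(max_used, lab))
    }
  }
  recurse(integer(n), 1, 0)
  out
}
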