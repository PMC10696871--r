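# Synthetic cohort, expression, and gene-resource generators.
#
# The generators emulate the statistical structure the downstream analyses
# assume: two patient subtypes with oppositely signed regional MSN-strength
# perturbations, covariate effects (age, sex, TIV) with smooth regional
# susceptibility patterns, spatially autocorrelated gene-expression maps with
# a planted gradient, marker sets enriched for planted genes, and DGE tables
# whose log2 fold changes track planted loadings. Every generator is a pure
# function of (configuration, seed) and returns the ground truth it planted.

#' Native-unit scales of the five morphometric features
#'
#' Means and SDs (per region, across the cortex) used to map the latent
#' z-space feature model into plausible native units: surface area (mm^2),
#' cortical thickness (mm), gray matter volume (mm^3), Gaussian curvature
#' (mm^-2), mean curvature (mm^-1).
#' @return data.frame with columns `feature`, `mean`, `sd`.
#' @export
feature_scales <- function() {
  data.frame(
    feature = msn_features(),
    mean = c(1200, 2.5, 3000, 0.15, 0.12),
    sd   = c(220, 0.25, 650, 0.045, 0.035),
    stringsAsFactors = FALSE
  )
}

# Shared latent feature direction: perturbations act along this unit 5-vector,
# because MSN strength responds monotonically to a region profile's projection
# onto the direction shared with other regions.
feature_direction <- function() {
  u <- c(1, 1, 1, -1, -1)
  u / sqrt(sum(u^2))
}

# Deterministic smooth fields on the parcellation sphere used as regional
# susceptibility patterns (standardized coordinates), plus the skewed
# alignment field that grades each region's projection onto the shared
# feature direction. The skew (many regions mildly aligned, few strongly
# anti-aligned) is essential: z-normalization removes the mean profile, and
# only an asymmetric alignment distribution leaves a nonzero mean
# unit-profile direction for MSN strength to respond to.
susceptibility_fields <- function(parcellation) {
  list(gradient = zscore(parcellation$z),
       alignment = zscore(-exp(1.3 * parcellation$z)),
       sex = zscore(parcellation$x),
       tiv = zscore(parcellation$y))
}

#' Default study-emulating cohort configuration
#'
#' Mirrors the scale and structure of the motivating cohort: 106 controls and
#' 100 patients split 53/47 between two planted subtypes whose regional
#' MSN-strength perturbations are opposite in sign region-by-region --
#' emulating the observed phenomenon of one subtype's case-control t-map
#' being roughly the inverse of the other's. Each subtype decreases strength
#' on one region set and increases it on a second, disjoint set; subtype 2
#' carries the mirrored pattern. The two sets are interleaved by rank of the
#' baseline alignment field (mid-range regions, where strength responds most
#' steeply to a perturbation), so their baseline-strength distributions are
#' matched and the between-subtype contrast is decorrelated from the
#' subject-level global strength factor. Effect magnitudes are in units of
#' the baseline feature SD and are a property of this stated configuration,
#' not of the analysis code.
#'
#' @param parcellation parcellation the region sets are defined on.
#' @param effect_magnitude strength perturbation size in baseline-SD units
#'   (default 2.5, a strong planted effect).
#' @param n_affected regions per signed set (each subtype perturbs
#'   `2 * n_affected` regions); defaults to 48 at the full 308-region scale
#'   and shrinks proportionally for smaller parcellations.
#' @return list accepted by [simulate_cohort()] as `subtype_config`, plus
#'   cohort sizes in `n_control` / `n_patient`.
#' @export
paper_default_config <- function(parcellation, effect_magnitude = 2.5,
                                 n_affected = NULL) {
  al <- susceptibility_fields(parcellation)$alignment
  R <- nrow(parcellation)
  n_affected <- n_affected %||% max(2L, as.integer(round(R * 48 / 308)))
  if (2L * n_affected > R) stop("n_affected too large for this parcellation")
  ord <- order(al)
  n_mid <- 2L * n_affected
  start <- max(1L, (R - n_mid) %/% 2L - n_affected %/% 2L)
  mid <- ord[seq(start, length.out = n_mid)]
  set_a <- parcellation$region_id[mid[seq(1L, n_mid, by = 2L)]]
  set_b <- parcellation$region_id[mid[seq(2L, n_mid, by = 2L)]]
  eff <- c(rep(-effect_magnitude, n_affected), rep(+effect_magnitude, n_affected))
  list(
    n_control = 106L,
    n_patient = 100L,
    proportions = c(0.53, 0.47),
    subtypes = list(
      list(regions = c(set_a, set_b), effect = eff),
      list(regions = c(set_a, set_b), effect = -eff)
    ),
    planted_n_subtypes = 2L
  )
}

#' Simulate a case-control morphometric cohort
#'
#' Per-subject region x feature tables are generated as a region-specific
#' baseline profile (five features in native units) plus covariate terms
#' (linear age, sex offset, TIV scaling, each acting along the shared feature
#' direction with a smooth regional susceptibility pattern), a subtype
#' perturbation for patients, and i.i.d. subject noise. Positive subtype
#' effects push the affected regions' feature vectors toward the shared
#' feature direction (raising downstream MSN strength), negative effects push
#' away from it.
#'
#' @param parcellation parcellation from [make_parcellation()].
#' @param n_control,n_patient group sizes.
#' @param subtype_config list with `proportions` (summing to 1) and
#'   `subtypes`, a list of `list(regions=, effect=)` entries; `effect` is a
#'   signed magnitude in baseline-SD units (scalar or per-region vector).
#' @param covariate_config optional list overriding the defaults:
#'   `age_mean, age_sd, age_range, sex_p, tiv_mean, tiv_sd` and effect sizes
#'   `beta_age, beta_sex, beta_tiv` (baseline-SD units).
#' @param noise_sd subject-level feature noise in baseline-SD units.
#' @param seed integer seed.
#' @return list with `features` (named list of region x feature matrices),
#'   `meta` (subject metadata data.frame; sex coded M/F, `sex01` gives the
#'   0/1 covariate coding M=0, F=1), and `truth` (a `GroundTruth` list).
#' @export
simulate_cohort <- function(parcellation, n_control, n_patient,
                            subtype_config, covariate_config = NULL,
                            noise_sd = 0.35, seed = 1L) {
  validate_parcellation(parcellation)
  R <- nrow(parcellation)
  props <- subtype_config$proportions %||% 1
  subs <- subtype_config$subtypes
  if (is.null(subs) || length(subs) < 1) stop("subtype_config needs >= 1 subtype")
  if (length(props) != length(subs)) stop("one proportion per subtype required")
  if (abs(sum(props) - 1) > 1e-8) stop("subtype proportions must sum to 1")
  for (s in subs) {
    if (length(s$regions) == 0) stop("empty subtype region set")
    if (!all(s$regions %in% parcellation$region_id))
      stop("subtype regions outside the parcellation")
  }

  cc <- utils::modifyList(list(
    age_mean = 14.6, age_sd = 2.2, age_range = c(7, 17), sex_p = 0.66,
    tiv_mean = 1465, tiv_sd = 140,
    beta_age = 0.3, beta_sex = 0.2, beta_tiv = 0.3,
    struct_noise = 0.35
  ), covariate_config %||% list())

  fs <- feature_scales()
  u <- feature_direction()
  fields <- susceptibility_fields(parcellation)
  n <- n_control + n_patient

  struct_noise <- cc$struct_noise
  with_seed(seed, {
    # latent baseline: each region's profile is its alignment-field value
    # along the shared direction plus independent within-profile structure
    Pz <- outer(fields$alignment, u) +
      struct_noise * matrix(stats::rnorm(R * 5), R, 5)
    baseline <- sweep(sweep(Pz, 2, fs$sd, "*"), 2, fs$mean, "+")

    # subtype sizes from proportions (largest-remainder rounding)
    raw <- props * n_patient
    sizes <- floor(raw)
    rem <- n_patient - sum(sizes)
    if (rem > 0) {
      ord <- order(raw - sizes, decreasing = TRUE)
      sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
    }
    subtype_truth <- c(rep(NA_integer_, n_control),
                       rep(seq_along(subs), sizes))

    age <- pmin(cc$age_range[2], pmax(cc$age_range[1],
                stats::rnorm(n, cc$age_mean, cc$age_sd)))
    sex01 <- stats::rbinom(n, 1, 1 - cc$sex_p)  # M = 0, F = 1
    tiv <- stats::rnorm(n, cc$tiv_mean, cc$tiv_sd)
    group <- rep(c("control", "patient"), c(n_control, n_patient))
    ids <- sprintf("S%03d", seq_len(n))

    std_age <- (age - cc$age_mean) / cc$age_sd
    std_tiv <- (tiv - cc$tiv_mean) / cc$tiv_sd

    features <- vector("list", n)
    names(features) <- ids
    for (i in seq_len(n)) {
      shift <- cc$beta_age * std_age[i] * fields$gradient +
        cc$beta_sex * sex01[i] * fields$sex +
        cc$beta_tiv * std_tiv[i] * fields$tiv
      if (!is.na(subtype_truth[i])) {
        s <- subs[[subtype_truth[i]]]
        eff <- rep_len(s$effect, length(s$regions))
        shift[s$regions] <- shift[s$regions] + eff
      }
      x <- baseline + outer(shift, u * fs$sd) +
        matrix(stats::rnorm(R * 5), R, 5) %*% diag(noise_sd * fs$sd)
      dimnames(x) <- list(parcellation$region_id, fs$feature)
      features[[i]] <- x
    }

    panss <- matrix(NA_real_, n, 4,
                    dimnames = list(NULL, c("panss_total", "panss_positive",
                                            "panss_negative", "panss_general")))
    pat <- group == "patient"
    panss[pat, 1] <- round(pmax(30, stats::rnorm(sum(pat), 60.9, 15.8)))
    panss[pat, 2] <- round(pmax(7, stats::rnorm(sum(pat), 15.0, 5.1)))
    panss[pat, 3] <- round(pmax(7, stats::rnorm(sum(pat), 14.1, 6.0)))
    panss[pat, 4] <- round(pmax(16, stats::rnorm(sum(pat), 31.8, 8.4)))
  })

  meta <- data.frame(
    subject_id = ids, group = group, subtype_truth = subtype_truth,
    age = age, sex = ifelse(sex01 == 1, "F", "M"), sex01 = sex01, tiv = tiv,
    panss, stringsAsFactors = FALSE
  )
  truth <- list(
    affected_regions = lapply(subs, function(s)
      data.frame(region = s$regions,
                 effect = rep_len(s$effect, length(s$regions)))),
    planted_n_subtypes = length(subs),
    subtype_sizes = sizes,
    seed = seed
  )
  list(features = features, meta = meta, truth = truth)
}

#' Simulate a spatially autocorrelated region x gene expression matrix
#'
#' Associated genes follow `beta_g * standardized(target_map) + noise_field`,
#' with the sign of `beta_g` set by the gene's class; all genes (associated or
#' not) receive a spatially correlated noise field with exponential angular
#' covariance `exp(-angle / corr_length)` over the region centroids, so spin
#' permutation nulls remain meaningful.
#'
#' @param parcellation_left left-hemisphere subset of a parcellation (rows
#'   with `hemisphere == "left"`), or any parcellation-like table with unit
#'   centroids.
#' @param target_map numeric vector over those regions (e.g. a t-map).
#' @param n_genes total genes.
#' @param frac_pos,frac_neg fractions of genes with positive / negative
#'   planted loadings (sum <= 1).
#' @param spatial_corr_length angular correlation length in radians
#'   (default 0.3).
#' @param noise_sd field noise SD.
#' @param beta_sd spread of planted |loading| around 1.
#' @param seed integer seed.
#' @return list with `expr` (region x gene matrix, rownames = region ids) and
#'   `truth` (named loading vector; 0 for unassociated genes).
#' @export
simulate_expression <- function(parcellation_left, target_map, n_genes,
                                frac_pos = 0.1, frac_neg = 0.1,
                                spatial_corr_length = 0.3, noise_sd = 1,
                                beta_sd = 0.2, seed = 1L) {
  R <- nrow(parcellation_left)
  if (length(target_map) != R) stop("target_map length must match regions")
  if (stats::sd(target_map) == 0) stop("degenerate target_map (zero variance)")
  if (frac_pos + frac_neg > 1) stop("frac_pos + frac_neg must be <= 1")
  cent <- as.matrix(parcellation_left[, c("x", "y", "z")])
  K <- exp(-angular_distance(cent) / spatial_corr_length)
  L <- chol(K + diag(1e-8, R))
  tstd <- zscore(target_map)

  with_seed(seed, {
    n_pos <- round(frac_pos * n_genes)
    n_neg <- round(frac_neg * n_genes)
    loading <- c(abs(stats::rnorm(n_pos, 1, beta_sd)),
                 -abs(stats::rnorm(n_neg, 1, beta_sd)),
                 rep(0, n_genes - n_pos - n_neg))
    names(loading) <- sprintf("G%05d", seq_len(n_genes))
    field <- crossprod(L, matrix(stats::rnorm(R * n_genes), R, n_genes))
    expr <- outer(tstd, loading) + noise_sd * field
  })
  dimnames(expr) <- list(parcellation_left$region_id, names(loading))
  list(expr = expr, truth = loading)
}

#' Simulate cell-type marker sets, an ISH screen list, and DGE tables
#'
#' Cell-type sets are drawn without replacement from the gene universe; sets
#' designated as enriched draw planted positive- or negative-loading genes
#' with the configured odds relative to null genes (odds 1 = uniform, so
#' overlaps follow the hypergeometric law). DGE tables carry
#' `log2fc = a * loading + noise` for genes overlapping the planted set and
#' pure noise otherwise.
#'
#' @param gene_names gene universe (names of the expression matrix columns).
#' @param loadings named planted-loading vector from [simulate_expression()].
#' @param set_size genes per cell-type set.
#' @param enrichment named character vector mapping a cell-type name to
#'   `"pos"` or `"neg"`; unnamed types are unenriched.
#' @param enrichment_odds sampling odds for target-class genes in enriched
#'   sets (default 8).
#' @param dge_config list: `disorders` (names), `n_genes` per table, slope
#'   `a`, `noise_sd`, and `frac_planted` (fraction of each table drawn from
#'   planted genes).
#' @param ish_size size of the ISH screen gene list (mix of planted and null
#'   genes).
#' @param seed integer seed.
#' @return list with `cell_sets` (named list of gene vectors), `ish_genes`,
#'   and `dge_tables` (named list of data.frames gene/log2fc/disorder).
#' @export
simulate_gene_resources <- function(gene_names, loadings,
                                    set_size = 50L,
                                    enrichment = c(excitatory_neurons = "pos",
                                                   inhibitory_neurons = "pos",
                                                   astrocytes = "neg"),
                                    enrichment_odds = 8,
                                    dge_config = list(
                                      disorders = c("ASD", "adult_SCZ", "BD",
                                                    "AAD", "MDD", "IBD"),
                                      n_genes = 120L, a = 1, noise_sd = 0.3,
                                      frac_planted = 0.5),
                                    ish_size = 40L, seed = 1L) {
  if (set_size >= length(gene_names)) stop("set_size exceeds gene pool")
  loadings <- loadings[gene_names]
  loadings[is.na(loadings)] <- 0
  names(loadings) <- gene_names
  cell_types <- c("endothelial", "astrocytes", "microglia", "oligodendrocytes",
                  "OPCs", "excitatory_neurons", "inhibitory_neurons")

  with_seed(seed, {
    cell_sets <- lapply(stats::setNames(cell_types, cell_types), function(ct) {
      w <- rep(1, length(gene_names))
      cls <- enrichment[ct]
      if (!is.na(cls)) {
        target <- if (cls == "pos") loadings > 0 else loadings < 0
        w[target] <- enrichment_odds
      }
      sample(gene_names, set_size, prob = w)
    })
    planted <- gene_names[loadings != 0]
    n_pl <- min(length(planted), ceiling(ish_size / 2))
    ish <- c(sample(planted, n_pl),
             sample(setdiff(gene_names, planted), ish_size - n_pl))
    dge_tables <- lapply(stats::setNames(dge_config$disorders,
                                         dge_config$disorders), function(d) {
      n_pl <- min(length(planted), round(dge_config$frac_planted * dge_config$n_genes))
      g <- c(sample(planted, n_pl),
             sample(setdiff(gene_names, planted), dge_config$n_genes - n_pl))
      data.frame(gene = g,
                 log2fc = dge_config$a * loadings[g] +
                   stats::rnorm(length(g), 0, dge_config$noise_sd),
                 disorder = d, stringsAsFactors = FALSE, row.names = NULL)
    })
  })
  list(cell_sets = cell_sets, ish_genes = ish, dge_tables = dge_tables)
}
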