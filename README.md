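# msnsubtype

Morphometric similarity network (MSN) subtyping and imaging transcriptomics
for case-control structural neuroimaging cohorts.

## The problem

Psychiatric case-control cohorts are heterogeneous: patients with one
clinical label can carry distinct, even opposite, patterns of cortical
change. This package implements a complete pipeline that (i) summarizes each
subject's cortical organization as a morphometric similarity network, (ii)
discovers neuroanatomical patient subtypes by how they differ from controls,
and (iii) links each subtype's regional abnormality map to brain-wide gene
expression, disease gene sets, cross-disorder differential expression, and
cell-type marker signatures. It is aimed at researchers with regional
FreeSurfer-style morphometry tables and AHBA-style expression data — and it
ships a synthetic cohort generator with planted ground truth so every stage
of the pipeline can be tested end to end.

## The model

* **MSN**: for each subject, regions are described by five T1-derived
  features (surface area, cortical thickness, gray matter volume, Gaussian
  curvature, mean curvature); features are z-normalized across regions and
  the network edge is the Pearson correlation `r_ij` between the two
  regions' feature profiles (no thresholding). Regional *strength* is
  `s_i = mean_{j != i} r_ij`.
* **HYDRA** (heterogeneity through discriminant analysis): K linear
  max-margin classifiers (faces of a convex polytope) jointly separate
  controls from patients, minimizing
  `sum_j [ ||w_j||^2/2 + C sum_ctl hinge(1 + w_j'x + b_j)/K +
  C sum_pat s_ij hinge(1 - w_j'x - b_j) ]`; patients cluster by their
  assigned face. Model order is chosen by cross-validated assignment
  stability (mean pairwise adjusted Rand index over fold pairs), scanning
  K = 2..10 with `C = 0.25`, 50 alternations, consensus initializations,
  tenfold CV.
* **Case-control statistics**: per region,
  `s_i = intercept + beta_g group + beta_1 age + beta_2 sex + beta_3 TIV`,
  two-sided t on `beta_g`, Bonferroni across regions.
* **Imaging transcriptomics**: PLS1 of the region x gene matrix against the
  t-map (for a univariate response the PLS1 weights are the normalized
  covariance vector `X'y`); inference by spatial (spin) permutations and by
  bootstrap gene Z scores (`Z = w / SE`, lists at `|Z| > 5`); gene-list
  screens against ISH disease genes (`|rho| > 0.35`, FDR), cross-disorder
  log2 fold changes (Spearman + permutation), and cell-type marker sets
  (ssGSEA regional scores and overlap permutation tests).

## Worked example

```r
library(msnsubtype)

# 1. Simulate a compact study-structured cohort (64 regions, 40 HC / 40 EOS)
parc <- make_parcellation(64, 32, seed = 1)
cfg  <- paper_default_config(parc)          # two mirrored planted subtypes
coh  <- simulate_cohort(parc, 40, 40, cfg, seed = 1)

# 2. MSN strengths and covariate residualization
S  <- cohort_strengths(coh$features)        # subject x region
Sr <- residualize_strengths(S, coh$meta)

# 3. HYDRA model-order scan and subtype fit
sel <- cv_ari(Sr, coh$meta$group, k_range = 2:4, folds = 5, seed = 1,
              n_consensus = 5)
print(sel)
fit <- hydra_fit(Sr, coh$meta$group, K = sel$chosen_k, n_consensus = 5, seed = 1)
truth <- coh$meta$subtype_truth[coh$meta$group == "patient"]
adjusted_rand_index(fit$assignments, truth)

# 4. Case-control t-map for subtype 1 vs controls
meta1 <- subtype_contrast_meta(coh$meta, fit$assignments, k = 1)
tmap  <- fit_region_glm(Sr[match(meta1$subject_id, rownames(Sr)), ], meta1,
                        case_level = "case")

# 5. Imaging transcriptomics on the left hemisphere
left   <- parc[parc$hemisphere == "left", ]
t_left <- tmap$t[left$region_id]
expr <- simulate_expression(left, t_left, n_genes = 500,
                            frac_pos = 0.1, frac_neg = 0.1, seed = 1)
pls  <- pls1(expr$expr, t_left)
spin_test(pls$scores, t_left, parcellation_centroids(left),
          n_rot = 1000, seed = 1)
zt    <- bootstrap_gene_z(expr$expr, t_left, B = 500, seed = 1)
lists <- threshold_gene_lists(zt)

# 6. Cell-type enrichment of the PLS1+ list
res <- simulate_gene_resources(names(expr$truth), expr$truth, seed = 1)
celltype_overlap_tests(lists$pos, res$cell_sets, names(expr$truth),
                       n_perm = 2000, seed = 1)
```

Output (abridged):

```
Cross-validated cluster stability (ARI):
 k       ari
 2 0.9499562
 3 0.8890990
 4 0.7635011
chosen K = 2
ARI vs planted truth: 0.81
regions with Bonferroni-significant strength change: 20 of 64
PLS1 explained variance: 0.99
spatial correlation of PLS1 scores with the t-map: rho = 0.98 , p_spin = 0.003
PLS1+ genes (Z > 5): 46   PLS1- genes (Z < -5): 47
          cell_type overlap       p_perm           q
 excitatory_neurons      25 0.0004997501 0.001749125
 inhibitory_neurons      19 0.0004997501 0.001749125
        endothelial       2 0.9670164918 0.994502749
 ...
```

Reading the numbers: the stability scan peaks at the planted two-subtype
solution; the consensus HYDRA fit recovers the planted partition with ARI
0.81; 20 of 64 regions pass Bonferroni in the subtype-1 contrast; PLS1
explains 99% of the t-map's variance in this high-signal synthetic world
and its score map spatially correlates with the t-map (rho = 0.98,
surviving the spin null); the bootstrap Z threshold extracts the planted
positive/negative gene programs, and the overlap tests flag exactly the two
cell-type sets that were generated with planted-gene enrichment
(excitatory/inhibitory neurons), with the unenriched sets near q = 1.

## Command line

```sh
Rscript -e 'msnsubtype::msn_cli()' simulate --seed 1 --out cohort/
Rscript -e 'msnsubtype::msn_cli()' msn --features cohort/features.tsv --out cohort/strengths.tsv
Rscript -e 'msnsubtype::msn_cli()' subtype --strengths cohort/strengths.tsv --meta cohort/meta.tsv --kmin 2 --kmax 10 --seed 1
Rscript -e 'msnsubtype::msn_cli()' stats --strengths cohort/strengths.tsv --meta cohort/meta.tsv --out cohort/tmap.tsv
```

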