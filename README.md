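# vaemarker

Biomarker discovery from bulk RNA-seq read counts, for tumor/normal cohorts
where the question is not just *which genes are differential* but *which
genes carry the class signal in (nearly) every sample*. A gene strongly
shifted in 30% of tumors and a gene moderately shifted in all of them can
show the same cohort-level fold change; only the second is a robust marker.
`vaemarker` separates the two by training a classifier and asking it, sample
by sample, which genes its decision relied on.

## The method

1. **Stability-resampled differential expression.** With *n* normals and
   ratio *r* (default 1:6), each of 1000 iterations keeps every normal and
   draws *r·n* tumors without replacement; a negative-binomial exact test
   (conditional on group totals, method-of-moments common dispersion) is run
   per iteration, and genes are ranked by the frequency with which they pass
   |log2FC| > 1, p < 0.05. Three nested feature sets result: all
   ever-significant genes, and those significant in ≥ 95% / ≥ 75% of
   iterations.

2. **A jointly trained VAE + MLP classifier.** Encoder widths
   1024/1024/512/128 (auto-scaled down for narrow inputs) to a 128-d
   Gaussian latent code with the reparameterization z = μ + σε; mirrored
   sigmoid decoder scored by binary cross-entropy plus the closed-form KL
   penalty; a 128/64/2 softmax head on z. Training runs 250 epochs in three
   phases - 50 VAE-only, 50 classifier-only (encoder frozen), 150 joint -
   minimizing λ·L_VAE + L_MLP with λ = 0.001.

3. **Expected-gradients attribution.** Signed per-sample, per-gene
   contributions to the tumor-class logit through the deterministic encoder
   mean, decomposing each prediction as
   y⁽ⁱ⁾ = y_base + Σ_j f(x_j⁽ⁱ⁾) against a training-cohort baseline.

4. **Biomarker potential score.** For cutoffs at significance level q
   (5%, 1%, 0.5%), C_P counts tumor samples with a significant positive
   contribution and C_N normal samples with a significant negative one;
   with P_tumor = C_P/N_tumor and P_normal = C_N/N_normal,

   Score(g) = 2 · P_tumor · P_normal / (P_tumor + P_normal)

   - the harmonic mean, which is zero unless the gene contributes in *both*
   classes. The top quartile per significance level survives, the three
   levels are intersected per run, and the final list is the intersection of
   all runs (sample sets × feature configurations).

5. **Prognostic step.** Univariate Cox screening of the final genes,
   a multivariate Cox risk model, the linear risk score
   RiskScore = Σ Coef_i · Exp_i, median-split High/Low grouping, and a
   log-rank comparison.

A negative-binomial simulator with planted differential genes and planted
fully penetrant biomarkers (ground truth recorded) makes every stage
testable without external data.

## A worked example

```r
library(vaemarker)

sim  <- simulate_counts(simulation_config(n_genes = 500, n_normal = 10,
                                          n_tumor = 60, n_de = 50,
                                          n_biomarkers = 10, seed = 1))
plan <- make_resampling_plan(sim$labels, n_iterations = 5, ratio = 6, seed = 2)
freq <- run_stability(sim$counts, sim$labels, plan)
sets <- build_feature_sets(freq, ceiling(c(0.95, 0.75) * 5))

split  <- vaemarker:::stratified_split(names(sim$labels), sim$labels, 0.8, 3)
scaled <- minmax_scale(count_matrix(sim$counts[sets[["Freq>=5"]]$gene_ids, ]),
                       split$train_ids)
model  <- vaejmlp_train(scaled, sim$labels,
                        schedule = training_schedule(seed = 4), split = split)
model
#> vaejmlp: 23 features -> encoder [23, 23, 12, 8] -> latent 8 -> mlp [8, 8] -> 2 classes
#>   trained 250 epochs (50 vae / 50 mlp / 150 joint), lambda = 0.001
#>   held-out AUC 1.000, accuracy 1.000

attr <- attribute_genes(model, scaled, seed = 5)
tab  <- score_genes(attr, sim$labels, compute_thresholds(attr, 0.01))
head(tab, 5)
#>     gene_id c_p c_n p_tumor p_normal score
#> 4  gene0041  58   9   0.967      0.9 0.932
#> 7  gene0097  52  10   0.867      1.0 0.929
#> 22 gene0464  57   8   0.950      0.8 0.869
#> 10 gene0125  49   9   0.817      0.9 0.856
#> 20 gene0453  41  10   0.683      1.0 0.812
```

Reading the table: `gene0041` contributes significantly toward the tumor
class in 58 of 60 tumors (P_tumor = 0.967) and toward the normal class in 9
of 10 normals (P_normal = 0.9); its score 0.932 is the harmonic mean of the
two proportions. All five top genes are planted fully penetrant biomarkers;
the top quartile here keeps 6 genes, all of them planted biomarkers (6 of
the 10 planted). Heterogeneous differential genes - shifted in only ~30% of
tumors - are capped at P_tumor ≈ 0.3 and fall below the quartile bound.

The one-call driver runs the whole cascade and returns the final list with
full provenance:

```r
res <- run_discovery(sim$counts, sim$labels,
                     discovery_config(n_iterations = 5, ratio = 6,
                                      n_sample_sets = 5, seed = 2))
res$final_genes
res$metrics          # one row per trained model: AUC, accuracy, ...
```

`run_pipeline(pipeline_config(...))` adds file I/O, the optional prognostic
step, and a JSON manifest (seeds, config, timings) that makes any run
reproducible. A thin command-line wrapper with `simulate`, `diffexp`,
`train`, `attribute`, `score`, `discover` and `risk` subcommands lives at
`inst/cli/vaemarker.R`.

## Scope

No FPKM/TPM conversion, batch correction, gene annotation, enrichment
analysis, or external-cohort download. The vignette
(`vignettes/biomarker-discovery.Rmd`) documents the model, the significance
conventions, the simulator's design and its limits, and the known fragility
of the many-way candidate intersection on small cohorts.
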