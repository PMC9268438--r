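# ginsengms

Geographic-origin discrimination of *Panax ginseng* batches from
UHPLC-Q-TOF-MS peak-area profiles.

Ginseng grown in Jilin (JL), Liaoning (LN) and Heilongjiang (HLJ) differs in
quality and ginsenoside composition, but the differences are too subtle for
pharmacopoeial content assays, and unsupervised chemometrics (PCA, PLS-DA)
typically fails to resolve the three provinces. `ginsengms` implements a
complete, reproducible pipeline for the task:

1. **Peak screening** — keep MS1 ions with area > 1000 counts, charge state
   1, quality score > 60.
2. **Alignment & common peaks** — greedy area-descending centroid clustering
   of per-sample peak lists (ppm m/z window, absolute RT window), then
   removal of features missing in more than 80% of samples.
3. **Ginsenoside annotation** — a packaged 69-record reference table of
   characteristic ginsenosides (formula, negative-mode adduct m/z, RT,
   MS/MS fragments); matching by theoretical `[M-H]-` / `[M+HCOO]-` masses
   with signed ppm error, and aglycone typing (PPT/PPD/OA) from the
   diagnostic fragments near *m/z* 475.38 / 459.38 / 455.35.
4. **Normalization** — mean normalization `x[k,m] / mean_k(x[k,m])` and
   Z-score normalization `(x[k,m] - mean) / sd` per feature.
5. **Baselines** — covariance-eigendecomposition PCA and NIPALS PLS-DA with
   R²Y, cross-validated Q², and a label-permutation test with R²/Q²
   intercepts.
6. **SVM** — a soft-margin RBF SVM written from its dual:

   maximize Σᵢ αᵢ − ½ ΣᵢΣⱼ αᵢαⱼ yᵢyⱼ K(xᵢ,xⱼ)  s.t.  0 ≤ αᵢ ≤ C, Σᵢ αᵢyᵢ = 0

   solved by SMO with maximal-violating-pair selection (compiled via Rcpp);
   bias b* from the free support vectors (which satisfy y f(x) = 1 at the
   optimum), one-vs-one multiclass voting, and a (C, γ) grid search under
   stratified ten-fold cross-validation.
7. **Quality markers** — permutation importance: the importance value of
   feature k is IV_k = s − mean_n(s_{k,n}), the drop in CV accuracy when
   column k is permuted (N repeats); markers are features with IV > 0,
   ranked by contribution. The SVM is refit on the marker panel and used to
   predict held-out market samples with the *training* normalization
   statistics.

Because the study's raw LC-MS data are not deposited, the package ships a
synthetic-data module (`synthetic_spec()`, `generate_feature_table()`,
`generate_peak_lists()`) that emulates the design — 31 training batches
(4 LN / 8 HLJ / 19 JL), 69 log-normal features with heterogeneous scales, a
planted set of origin-discriminative features, and sporadic missingness —
so every stage is testable end to end.

## Worked example

```r
library(ginsengms)

spec <- synthetic_spec(seed = 42)            # 31 batches, 69 features
pls  <- lapply(generate_peak_lists(spec), screen_peaks)
ft   <- filter_common_peaks(align_peaks(pls))
ft
#> <feature_table> 31 samples x 69 features; origins: HLJ=8 JL=19 LN=4; 2.0% zeros

z  <- normalize_zscore(ft)
gs <- grid_search(z, ft$origins, seed = 42)
cv_raw <- cross_validate(ft, C = gs$best_C, gamma = gs$best_gamma, seed = 42)
cv_z   <- cross_validate(z, ft$origins, C = gs$best_C, gamma = gs$best_gamma, seed = 42)
accuracy_from_pairs(ft$origins, cv_raw$predicted)   # 61   (raw peak areas)
accuracy_from_pairs(ft$origins, cv_z$predicted)     # 93   (Z-scored)

imp <- permutation_importance(z, ft$origins, C = gs$best_C,
                              gamma = gs$best_gamma, N = 10, seed = 42)
markers <- select_markers(imp)
refit   <- refit_on_markers(z, ft$origins, markers, seed = 42)
refit$report$accuracy
#> 100

test_ft <- generate_feature_table(spec, n_per_class = c(1, 2, 5),
                                  sample_seed = 1042, sample_prefix = "T")
predict_external(refit$model, test_ft, norm_stats = z)
#>  sample actual recognized
#>     T01     LN         LN
#>     T02    HLJ        HLJ
#>     ...
#> Accuracy = 100%
```

The raw-vs-normalized contrast (61% vs 93% here) is the pipeline's central
observation: Z-scoring removes the arbitrary per-feature intensity scales
that otherwise dominate the RBF kernel. The marker panel then carries the
full discrimination (100% ten-fold CV) and generalizes to the held-out
batches.

Annotation works the same way on any feature table:

```r
db   <- load_ginsenoside_db()        # 69 records, masses recomputed from formulas
hits <- annotate_features(ft, db, mz_tol_ppm = 15, rt_tol = 0.5)
```

`run_pipeline(pipeline_config(out_dir = "run1"))` executes all stages in
order and writes every artifact (feature table, annotation hits, normalized
tables, PCA/PLS-DA summaries, grid surface, training and test reports,
importance table, marker model as JSON) plus a checksum manifest.

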