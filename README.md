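# mtorresponse

An R implementation of an integrative machine-learning biomarker for
predicting clinical response to everolimus (an mTOR-complex inhibitor) in
ER+/HER2- breast cancer, together with seeded synthetic-data generators so
the whole pipeline can be exercised and tested without any external
download.

## The problem and the approach

Everolimus improves outcomes in advanced ER+ breast cancer, but no
biomarker guides its use: clinical cohorts with pre/post-treatment genomic
data are tiny (tens of patients), far too small to learn a transcriptomic
predictor directly. The package implements a hybrid strategy that
compensates for the small clinical sample with a well-controlled in vitro
experiment:

1. **In vitro signature.** Cell lines are profiled under vehicle control
   and drug treatment. After low-information filtering (variance ≤ 25th
   percentile or mean expression ≤ 30th percentile removed) and quantile
   normalization, the 100 genes most correlated with treatment status are
   selected (50 with the most positive and 50 with the most negative
   Pearson *r* against the 0/1 treatment label). The signature matrix is
   summarized by its first two singular vectors ("metagenes"); each
   sample's metagene scores *f* enter a Bayesian probit regression

   P(treated | f) = Φ(β₀ + β₁f₁ + β₂f₂),  β ~ N(0, τ²I), τ² = 100,

   fitted with the Albert–Chib latent-variable Gibbs sampler. Posterior
   predictive probabilities carry 95% intervals from the draw-level
   probabilities, and the signature is validated by leave-one-out
   cross-validation (LOOCV) over the cell-line samples.

2. **Integrative patient model.** Patients are labelled responders when
   their Ki67 staining falls by more than 10% of baseline. Inside a
   patient-level LOOCV, each training fold is discretized (per-gene median
   split) and the Fast Correlation-Based Filter (FCBF) selects clinical
   features by symmetrical uncertainty SU(X,Y) = 2·I(X;Y)/(H(X)+H(Y)) with
   predominance-based redundancy removal. The FCBF genes are fused with
   the in vitro signature and a random forest is trained on the fold, its
   `mtry` hyperparameter tuned by repeated stratified inner
   cross-validation. The held-out patient is scored by the fraction of
   trees voting "responder". No step ever sees the held-out column.

3. **External scoring.** The final model (FCBF + forest on all patients)
   scores an external cohort; per-group predicted probabilities are
   compared by one-way ANOVA with Tukey-HSD adjusted pairwise tests, plus
   the fraction of each group above a 0.75 high-response cutoff.

Because the original accessions (a neoadjuvant trial cohort and a large
external breast-cancer cohort) require downloads, the package ships
generators that emulate the two study designs — 9 paired cell lines with a
known treatment-responsive gene set, and a 23-patient cohort whose binary
response is driven by a small informative gene set with redundant
correlated copies — with full ground truth for testing.

## Worked example

A reduced end-to-end run (1,000 genes, 16 patients; a few seconds):

```r
library(mtorresponse)

cfg <- pipeline_config(seed = 7, n_genes = 1000, n_true_genes = 100,
                       n_patients = 16, n_iter = 2000, n_burn = 500,
                       n_trees = 200, inner_repeats = 2,
                       external_n_per_group = 30)
res <- run_full_pipeline(cfg)

glance(res$signature_model)
#>   n_genes  n_up n_down k_metagenes n_draws
#> 1     100    50     50           2    1500

glance(res$cellline_loocv)
#>       n n_correct accuracy majority_rate
#> 1    18        18        1           0.5

glance(res$patient_loocv)
#>       n n_correct accuracy majority_rate
#> 1    16        16        1           0.5

res$final_model
#> <integrated_model> 101 features (100 invitro / 1 fcbf / 0 both), mtry = 5, 200 trees

res$group_comparison
#> <group_comparison> one-way ANOVA F = 132 (p = 4.54e-27), 3 groups
#>   group      n mean_prob frac_high
#> 1 high      30     0.635    0.0333
#> 2 low       30     0.344    0
#> 3 medium    30     0.503    0
```

Reading the output: the in vitro stage recovered a balanced 100-gene
signature and classified all 18 cell-line samples correctly in LOOCV; the
integrative model classified all 16 synthetic patients correctly
out-of-fold; and on the simulated external cohort the predicted response
probabilities rise monotonically across the three planted risk groups,
with all Tukey-adjusted pairwise p-values below 1e-9.

Each result has `tidy()`, `glance()` and `autoplot()` methods —
`autoplot(res$patient_loocv)` draws the out-of-fold probabilities with
their 95% intervals against the 0.5 decision midline, and
`autoplot(res$external_scores)` the per-group probability boxplots.

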