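# trajsmm

Latent trajectory classification for longitudinal measurements via a
**smoothing mixture model (SMM)**: a hard-assignment EM algorithm whose class
means are penalized-spline (P-spline) smoothers, with BIC-based selection of
the number of classes and a downstream logistic-regression stage estimating
crude and adjusted odds ratios of binary outcomes across the identified
classes.

The package is aimed at biostatisticians and epidemiologists working with
repeated measurements — the motivating case is maternal weight measured
monthly over the nine months of pregnancy, where subgroups of women follow
distinct weight paths (low / medium / high) that carry different risks of
adverse pregnancy outcomes. Because cohorts of this kind are rarely shared,
the package also ships a synthetic-cohort generator that reproduces the
assumed data structure with ground-truth labels, so every stage of the
pipeline can be validated end to end.

## The model

For subject $i$ in latent class $k$, observed at months $t = 1, \dots, 9$:

$$ y_{it} = f_k(t) + b_i + \varepsilon_{it},
   \qquad b_i \sim N(0, \sigma_{b,k}^2),
   \quad \varepsilon_{it} \sim N(0, \sigma_k^2), $$

with $f_k$ a cubic P-spline (second-order difference penalty, GCV-selected
smoothing). Fitting alternates:

* **M step** — refit each class's smoother on its members' pooled
  observations; re-estimate variance components by method of moments;
* **E step** — reassign each subject to the class under whose model its
  observations have the largest marginal (compound-symmetry) log-likelihood,

until memberships and the total log-likelihood are both stable. The number
of classes minimizes BIC over a candidate range, with a parsimony margin
that prefers a smaller class count whose BIC is within 3.5% of the minimum.
Odds ratios use dummy-coded classes with the medium trajectory as reference,
Wald intervals, and a univariate p < 0.2 confounder screen for the adjusted
models.

## Worked example

```r
library(trajsmm)

gen <- generate_cohort(cohort_config(seed = 1))   # 877 subjects, 9 months, 3 classes
fit <- relabel(fit_smm(gen$data, 3))
fit
#> Smoothing mixture model: K = 3, 877 subjects, 7893 observations
#>   total log-likelihood -12887.64, BIC 25961.37 (p = 20.7)
#>   8 iteration(s), converged: TRUE
#>   class sizes: low=333, medium=297, high=247

adjusted_rand_index(fit$assignment[names(gen$labels)], gen$labels)
#> [1] 0.868
```

The fit recovers the three generating classes up to the noise-imposed
ceiling (subjects near a class boundary are genuinely ambiguous at the
default noise level: the Bayes-optimal assignment itself reaches ARI ≈ 0.91
on these cohorts). Class-count selection over K = 2..5:

```r
sel <- select_k(gen$data, 2:5)
sel$table[, c("K", "bic", "class_medians")]
#>  K      bic                                               class_medians
#>  2 26765.96                                      62.9 (2.7); 73.6 (7.9)
#>  3 25961.37                          62.9 (2.7); 71.1 (2.5); 79.3 (3.5)
#>  4 25621.02              62.0 (1.6); 65.1 (2.1); 71.5 (2.6); 79.4 (3.2)
#>  5 25308.31  62.0 (1.5); 65.1 (2.1); 70.6 (1.2); 73.4 (2.1); 79.6 (2.9)
sel$parsimony_note
#> "K = 3 selected on parsimony: BIC within 3.5% of the minimum at K = 5"
```

BIC alone keeps drifting down as classes are added (a known behaviour of
flexible-smoother mixtures); the parsimony margin recovers the three-class
description, whose medians sit at the generating 63 / 71.5 / 79.5 kg levels.
Outcome associations:

```r
covs <- generate_covariates(names(gen$labels), seed = 2)
outs <- generate_outcomes(gen$labels, covs, outcome_config(seed = 3))
res  <- run_association(fit$assignment, outs)
res[res$outcome == "composite_neonatal" & !res$adjusted,
    c("contrast", "estimate", "ci_low", "ci_high", "p_value")]
#>        contrast estimate ci_low ci_high  p_value
#>   low vs medium     2.01  1.460    2.76 1.77e-05
#>  high vs medium     1.19  0.851    1.68 3.04e-01
```

The low-weight trajectory carries a significantly elevated odds of composite
neonatal events versus the medium trajectory, as configured in the
generator; the high-vs-medium contrast is null.

`run_pipeline(run_config(...))` chains all stages (descriptives with
normality checks, selection, relabeling, baseline-grouping concordance,
odds ratios, figures) and writes CSV/JSON artifacts plus a markdown report.
A thin command-line front end with `simulate` / `fit` / `associate` / `run`
subcommands is installed under `inst/cli/trajsmm`.

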