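# rocrestrict

Dataset restriction for biomarker discovery: restricted ROC curves, the
sample-size standardised restricted AUC (rzAUC), optimal informative
ranges with permutation significance, classification on classifiable
samples only, restriction-aware random forests, and a generative flow
cytometry simulator (Dirichlet gating tree + per-leaf Gaussian antigen
models) for validating all of it.

## Why

Disease biomarkers — cell-subset frequencies in particular — are often
informative only over part of their range. When the patient class is more
dispersed than the control class (say controls $\mathcal N(5,1)$ vs
patients $\mathcal N(6,2)$), the ROC curve crosses the diagonal: high
values discriminate while low values *consistently misclassify*. The
full-curve AUC then buries a usable marker.

For a marker $Y$ with labels $D \in \{0,1\}$, every observed value $r$
splits the cohort into $\{Y > r\}$ (high) and $\{Y \le r\}$ (low). Each
part's restricted AUC is the corresponding two-way partial area of the
full ROC curve rescaled to the unit square,

$$\mathrm{rAUC}_{high}(r) = \mathrm{AUC}_{high}(S_{\bar D}(r)) \cdot
  \tfrac{1}{S_{\bar D}(r)} \tfrac{1}{S_D(r)},$$

which equals the plain AUC computed on that part's samples alone. Parts
of different sizes are compared via the standardised score

$$\mathrm{rzAUC}_X(r) = \frac{\mathrm{rAUC}_X(r) - 0.5}
  {\sqrt{(m_X + n_X + 1)/(12\, m_X n_X)}},$$

with $m_X, n_X$ the part's class counts (a Mann–Whitney null-variance
standardisation). The optimal restriction maximises
$|\mathrm{rzAUC}_X(r)|$ over all candidates and both parts; it defines
the marker's informative range, and samples outside it are
*unclassifiable*. Because the optimum is selected by maximisation, its
significance is assessed by label permutation (the maximisation is
repeated inside every shuffle), with Benjamini–Hochberg correction across
markers.

## Worked example

A 2500 + 2500 mixture in which 20% of positives and 2% of negatives carry
an elevated component ($\mathcal N(9,1)$ over a $\mathcal N(6,1)$
baseline):

```r
library(rocrestrict)
d <- simulate_two_class(two_class_scenarios()$large_mixture, seed = 1)
fit <- rroc(d$value, d$class, n_permutations = 500, seed = 1)
fit
#> Restricted ROC fit
#>   2500 positive / 2500 negative samples; unrestricted AUC = 0.5797
#>   optimal restriction: r = 6.913, part = high (keeps 1401 of 5000)
#>   informative range: (6.913, Inf)
#>   rAUC = 0.7118, rzAUC = 13.440
#>   permutation p-values (500 shuffles): unrestricted 0.001996, restricted 0.001996
```

The full-curve AUC is a weak 0.58, but above the fitted restriction
(≈6.9 for this draw; the optimum of this flat-profiled mixture scatters
by a few tenths between draws) the marker separates classes with a
restricted AUC of 0.71 over 1401 retained samples, significant under
permutation. `predict(fit, newdata)` then flags unclassifiable samples
and classifies the rest with a Youden cutoff fitted on classifiable
training samples; `plot(fit)` draws the rzAUC profile of both parts.

The same machinery runs on simulated flow cytometry cohorts: build a
gating tree (`example_gating_tree()`, or `read_gating_tree()` from
JSON), inject a disease effect into any population — either
precision-preserving to an exact target mean (`adjust_effect()`) or by
setting its Dirichlet parameter (`set_dirichlet_parameter()`) — simulate
cells (`simulate_cells()`), gate them (`apply_gating()`), and screen all
extracted population frequencies (`rroc_screen()`). Model estimation
from cell data is available via `estimate_dirichlet()`,
`estimate_leaf_gaussians()` and `fit_gating_model()`; multivariate
modelling via `fit_restriction_map()`, `restrict_transform()` and
`rroc_forest()`.

See `vignettes/restricted-roc.Rmd` for the model details, numerical
choices and known limitations.

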