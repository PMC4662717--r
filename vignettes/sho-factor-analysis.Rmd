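---
title: "Linking herbal formula composition and MS fingerprints to the Sho diagnostic axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking herbal formula composition and MS fingerprints to the Sho diagnostic axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shofactor)
```

## The problem

Kampo, the traditional Japanese herbal medicine system, prescribes fixed
combinations of crude drugs (plant, animal and mineral materials) as
formulas. The prescribing decision is anchored in *Sho*, a holistic
diagnosis of the patient's constitution with three states: Deficiency
(*Kyo*, weakness/hypoactivity), Middle (*Kang*, neutrality) and Excess
(*Jitsu*, robustness/hyperactivity). Two data views can be related to
this axis:

* **Composition matrices.** Formula *i* is a vector
  $x_i = (x_{i1}, \dots, x_{iM})$ of crude-drug quantities, giving an
  $N \times M$ non-negative matrix $X$. The matrix is sparse — a formula
  typically combines around ten of the hundred-plus drugs in use — and
  dense in encoding: an absent drug is 0, never missing.
* **Spectral fingerprints.** A decoction of a prescription, infused
  directly into a positive-ESI Q-TOF mass spectrometer, yields one
  composite spectrum per sample. Summing centroided peak intensities in
  fixed 0.5-m/z windows from 85.0 to 1199.5 produces a 2,230-bin
  intensity vector, the prescription's chemical fingerprint.

`shofactor` implements the full chain from either view to a
Deficiency/Excess discrimination: binning, PCA diagnostics,
discriminating-axis selection, PLS1 discriminant regression with
cross-validated component selection, and recognition-rate reporting. A
synthetic-data generator with planted class structure makes the whole
chain testable without access to the proprietary formula registry or the
original spectra.

## Spectral binning

`bin_grid(85, 1199.5, 0.5)` defines bins as half-open intervals
$[e_b, e_b + w)$ — the standard histogram convention, chosen so that no
peak is double-counted and a peak sitting exactly on an edge belongs to
the bin that starts there. The last bin covers $[1199.5, 1200)$,
matching an acquisition ceiling of m/z 1,200. "Integration" is
summation of centroided peak intensities per bin; with direct infusion
there is no chromatographic axis to integrate over. Peaks outside the
grid are discarded and counted, not clipped into the edge bins, so the
total-intensity balance of a run is always auditable. Total-ion-current
normalization is available (`tic_normalize()`) but off by default: the
analysis operates on raw binned intensities.

## PCA diagnostics

`fit_pca()` computes principal components by SVD (through
`stats::prcomp`). Each loading vector $b_k$ has unit Euclidean norm
($\sum_j b_{kj}^2 = 1$), scores are uncorrelated, and the **proportion**
$\Pr(Z_k) = \mathrm{Var}(Z_k) / \sum_l \mathrm{Var}(Z_l)$ summarizes
each axis. The **factor loading** $r(Z_k, X_j)$ is the Pearson
correlation between the $k$-th score and the $j$-th original variable,
the interpretable link back to individual crude drugs or m/z bins.

Principal component signs are inherently ambiguous; we fix each
component by making its largest-magnitude loading entry positive, so
repeated runs are bit-identical.

`select_discriminating_axes()` finds the axes that separate the two
poles of the Sho axis: candidates are the components explaining strictly
more than 1 % of variance (`variance_threshold = 0.01`); each
candidate's scores are compared between Deficiency and Excess rows with
a two-sided two-sample t-test; the two smallest p-values win, ties
resolving to the lower component index. Middle rows take part in the
PCA fit (they are genuine data) but not in the t-tests, since the
contrast of interest is the Deficiency/Excess dichotomy. Welch's
unequal-variance test is the default — class score variances have no
reason to be equal — with the pooled test available by flag; on planted
synthetic data the choice does not change the top-2 identity.

## PLS1 discrimination

Deficiency is coded $y_i = -1$ and Excess $y_i = +1$; Middle rows are
dropped before fitting, and drug columns that become all-zero in the
two-class subset are dropped with a log (the modelled variable set
shrinks exactly the way the class restriction implies). The model is
single-response partial least squares fitted by NIPALS:

$$\mathbf{y} = \bar{\mathbf{y}} + \sum_{k=1}^{A} \mathbf{t}_k q_k + \mathbf{e},
\qquad
\mathbf{X} = \bar{\mathbf{X}} + \sum_{k=1}^{A} \mathbf{t}_k \mathbf{p}_k^{\mathsf T} + \mathbf{E}.$$

Per component: weight $w_k \propto E^{\mathsf T} f$ (unit norm), score
$t_k = E w_k$, loadings $p_k = E^{\mathsf T} t_k / t_k^{\mathsf T} t_k$
and $q_k = f^{\mathsf T} t_k / t_k^{\mathsf T} t_k$, then deflation of
both residuals. For a single response this is fully deterministic — no
iteration, no random start. The equivalent coefficient form
$y = b_0 + \sum_j b_j X_j$ is assembled as
$b = W (P^{\mathsf T} W)^{-1} q$; the test suite asserts that both
prediction routes agree to $10^{-10}$, and that at full rank the fit
collapses onto ordinary least squares. A positive $b_j$ marks a drug
used more for Excess, a negative one for Deficiency — interpretable even
under the collinearity that breaks plain multiple regression, which is
the reason PLS is used here at all.

The component count $A$ maximizes

$$Q^2 = 1 - \frac{\sum (y_\mathrm{obs} - y_\mathrm{pred})^2}{\sum y_\mathrm{obs}^2},$$

computed from cross-validated predictions. The denominator is
deliberately uncentered: with a $\pm 1$ response it equals $N$, and a
constant-zero prediction scores exactly 0. Cross-validation is
leave-one-out by default (exact and affordable at these sample sizes),
with stratified 7-fold as an option for larger runs; folds are assigned
round-robin within each class, so they are deterministic without any
random draw. Ties in the $Q^2$ curve resolve to the smaller $A$. If a
training fold's residual covariance is exhausted before the requested
maximum (common when $N \ll M$, as with 31 samples over 2,230 bins),
the fold's coefficient sequence simply stops growing; requesting an
over-rank $A$ directly in `fit_pls1()` is an error.

Classification reads the sign of the predicted $y$: negative is
Deficiency, positive Excess. An exact zero — a measure-zero event
needing a fixed rule — classifies as Excess and is flagged. The
**recognition rate** is the fraction of sign-correct rows, and
misclassified samples are always reported by id. `coefficient_table()`
reports each drug's $b$, its usage count and usage percentage
($100 \cdot n / N$, half-up to two decimals), filtered to $|b| > 0.1$
and laid out negative block ascending, then positive block descending.
`refit_excluding()` supports sensitivity re-runs: drop named samples,
re-select $A$, refit, and compare recognition.

## The synthetic generator

The generator plants a known Deficiency/Excess signal so that every
stage has a recoverable ground truth.

* **Formulas.** Class drawn from the registry-scale frequencies
  382 : 218 : 226 (Deficiency : Middle : Excess, the class split of an
  826-formula registry); each of the 120 drugs included Bernoulli with
  base rate $10/120$ (about ten drugs per formula); five Excess-linked
  and five Deficiency-linked effect drugs have their inclusion
  probability boosted by 0.35 in their class and suppressed toward 0 in
  the opposite class; included drugs draw log-normal quantities
  (meanlog 1, sdlog 0.5 — gram-scale doses around 2.7 g). Usage, not
  quantity, carries the planted signal: real use-rate tables show
  exactly this kind of presence/absence asymmetry between classes.
* **Fingerprints.** 34 samples (19/3/12 class split, mirroring the
  published prescription panel), baseline intensity 100 with Gaussian
  noise (sd 20) clipped at zero, and 50 informative bins shifted by
  $\pm$shift/2 (default 60) according to class, each bin's direction
  drawn once and recorded.

A single root seed derives three independent sub-streams (class draw,
inclusion/bin placement, quantities/noise), so changing one mechanism
leaves the other draws untouched. What the generator does **not**
emulate: real crude-drug co-occurrence structure (classic drug
pairings), heavy-tailed intensity distributions, isotope envelopes and
adduct correlations between bins, or label noise in the registry
(available as a knob, default 0). Passing tests therefore demonstrate
algorithmic correctness and recoverability of planted effects — not
field performance on real registries or spectra.

## Validation problem sizes

The test suite validates the algebra on small matrices (up to
$10 \times 10$ against eigendecomposition and least-squares oracles) and
the pipeline on generated data at the generator defaults
($600 \times 120$ formulas) with stratified 7-fold CV for the component
search; axis-recovery and null-behaviour properties are checked over 20
seeds, the latter on 34-sample fingerprints over a 200-bin grid with
leave-one-out CV. These sizes give stable pass/fail behaviour while
keeping a full run in seconds.

## Known limitations

* The discriminant treats Sho as a dichotomy; Middle is never predicted,
  only excluded (matching how the axis is used diagnostically, but a
  three-class treatment is out of scope).
* Whether published recognition rates of this kind of analysis are
  in-sample or cross-validated is often ambiguous; this package reports
  the in-sample rate of the $Q^2$-selected model and keeps the
  cross-validated curve alongside, so both readings are available.
* Raw quantities are analysed unscaled by default (centering only). For
  fingerprint PCA both centered-only and autoscaled variance proportions
  are reported, since the appropriate preprocessing for a given
  instrument's intensity scale is a judgement call.
* No peak picking, centroiding or vendor-format parsing: inputs are
  peak lists or pre-binned matrices.
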