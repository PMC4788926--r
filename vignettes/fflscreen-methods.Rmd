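---
title: "Methods: from CT values to feed-forward-loop modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from CT values to feed-forward-loop modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflscreen)
```

`fflscreen` analyses small knockdown screens measured on qRT-PCR array
cards and reconstructs putative multi-output feed-forward-loop (FFL)
regulatory modules from pairs of silenced candidate modulators. This
vignette explains the statistical model behind each stage, the tunable
parameters and their defaults, the numerical choices, what the synthetic
generator does and does not emulate, and the known limitations.

## The measurement model

qRT-PCR reports, per well, a cycle threshold CT: the amplification cycle at
which fluorescence crosses a fixed threshold. CT is on a log2 scale of
transcript abundance and *higher CT means lower expression*. The
comparative-CT method converts CT values into relative expression without
standard curves, assuming near-perfect amplification efficiency:

* per sample, \(\Delta CT = CT_{gene} - CT_{ref}\), which removes
  sample-level loading and RNA-quantity effects through a reference gene
  shown to be stable across conditions;
* per knockdown (KD) condition,
  \(\Delta\Delta CT = \Delta CT^{KD} - \Delta CT^{CTRL}\), which removes
  gene-level baselines through the calibrator-siRNA control;
* relative expression \(FC = 2^{-\overline{\Delta\Delta CT}}\), so
  \(\Delta\Delta CT > 0\) means the gene is *down*-regulated under the
  knockdown.

Two exact invariances follow and are property-tested: adding a per-sample
constant to every gene leaves all ΔCT differences unchanged, and swapping
the KD and control roles negates every ΔΔCT.

**Reference-gene choice.** Among the candidate housekeeping genes, the one
with the smallest pooled standard deviation of raw CT across all samples is
selected (`select_reference_gene()`), ties broken by candidate order. The
pooled SD is a deliberately simple stability score: with ~10–100 samples
per screen, more elaborate stability measures (pairwise-variation schemes)
add little and require denser candidate panels; the metric is isolated in
one function and can be swapped.

**Replicate pairing.** ΔΔCT is computed per biological replicate by
matching KD replicate *i* to control replicate *i* within the same time
point (the default), which keeps K independent ΔΔCT values per cell for
variance estimation. Nothing in the assay links KD and control replicates
physically, so a `"mean_control"` policy (subtract the control-stratum mean
ΔCT) is offered; it shrinks the apparent replicate spread because the
control noise is averaged rather than propagated, and is intended for
sensitivity analysis rather than as the default.

**Missing wells.** "Undetermined" wells (no amplification before the
`ct_max = 40` cycle ceiling) become missing values at read time. Any
missing term of a replicate's ΔΔCT removes that replicate (K decreases); no
imputation is attempted, because an undetermined well can mean either a
truly absent transcript or a technical dropout, and the two cannot be
distinguished at this panel size. Cells with K = 0 are dropped and counted.

**Time 0 h.** The pre-stimulation baseline is retained in all tables but
excluded from significance testing by default (`test_times`), since
modulator effects are defined relative to the stimulated response.

## The error model of ΔΔCT variance

With K = 2 replicates, per-cell sample variances are hopeless estimates of
the biological variance (a scaled one-degree-of-freedom chi-square). The
package therefore borrows strength across the whole screen with the
flexible family

\[\hat\sigma^2(\Delta\Delta CT) = \alpha + \beta\,|\Delta\Delta CT|^\gamma,\]

which links variance to signal intensity; \(\alpha,\beta \ge 0\) and
\(\gamma \in [0, 4]\) keep the surface non-negative and non-decreasing in
\(|\Delta\Delta CT|\) (the bound of 4 is far above any exponent a qPCR
variance trend plausibly shows, and is configurable).

Fitting is done on *binned* data: the (|mean ΔΔCT|, sample variance)
records of all cells with K ≥ 2, pooled across silencing experiments, are
sorted by intensity and split into `n_bins = 10` equal-count bins
(min 3 records each; any remainder goes to the leftmost bins), and bin-mean
variances are regressed on bin-mean intensities by weighted least squares
with weights equal to the bin counts. Binning first and count-weighting the
averaged points is the natural way to stabilize the raw chi-square noise
while keeping the weighted residual sum of squares (WRSS) comparable across
variants; a raw-data mode (`binned = FALSE`) exists for sensitivity
analysis. Pooling across experiments is the default because per-experiment
record counts are small; per-experiment fits are available through the
`perturbations` argument.

Three nested variants are compared: **constant** (\(\beta = 0\); the
closed-form count-weighted mean of bin variances), **linear**
(\(\gamma = 1\)), and **power** (\(\gamma\) free; `"full"` is accepted as a
synonym for this fully parameterized model). The nonlinear variants use
bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) started
from the data range, with asymptotic standard errors from the WLS
information matrix. Selection operationalizes "best WRSS *and* precise
estimates": fits whose every free parameter has a coefficient of variation
above `cv_max = 0.5` are screened out (a parameter estimated to within only
±100 % is not evidence for its variant), then the smallest WRSS wins, with
ties going to fewer parameters. If nothing passes the screen the most
parsimonious converged fit is returned flagged `degraded`. On flat variance
data this reliably selects the constant model; the nesting
WRSS(power) ≤ WRSS(linear) ≤ WRSS(constant) is property-tested to optimizer
tolerance.

## The two-stage selection procedure

Per silencing experiment:

1. **Variance filter.** Cells whose replicate sample variance strictly
   exceeds the 95th percentile of that experiment's variance distribution
   are removed. The percentile is pinned to the nearest-rank definition
   (the value at index \(\lceil q/100 \cdot n\rceil\) of the sorted
   variances) so the filter is exact and platform-independent: with n a
   multiple of 20 and distinct values, exactly 5 % of cells are removed.
   Ties at the threshold are retained, and with fewer than 20 defined
   variances the filter is skipped with a warning rather than applied to a
   meaningless percentile. Filtering is per experiment, not pooled, so one
   noisy experiment cannot relax another's threshold.

2. **Model-based z-test.** For each unfiltered (gene, time point) cell the
   null H0: ΔΔCT = 0 is tested assuming
   \(\overline{\Delta\Delta CT} \sim N(0, \hat\sigma^2 / K)\), with
   \(\hat\sigma^2\) *always* the model-predicted variance at the observed
   ΔΔCT — never the per-cell sample variance, which is used only for
   filtering and model fitting. This is the procedure's central idea: the
   test borrows a stable variance estimate from the whole screen. The
   p-value is the two-sided normal tail \(2(1 - \Phi(|z|))\), and is
   verified in the tests against numerical integration of the normal
   density to 1e-10.

3. **Bonferroni correction.** \(p_{adj} = \min(1, m\,p)\) with m the number
   of tests *performed* in that experiment (post-filter; a `pre_filter`
   policy is available since the stricter choice of m is not forced by the
   procedure). Significance is \(p_{adj} \le 0.05\). Family-wise error
   control is verified empirically: over 1000 simulated global-null screens
   at the study scale (96 genes × 3 time points, K = 2, constant variance
   0.3975) the fraction of screens with any significant call stays at or
   below 0.05.

The perturbed gene's own cells trivially reflect the silencing itself, so
they are excluded from target calls and reported separately as a
knockdown-efficiency diagnostic. Two-sidedness follows from the screen's
purpose: both down- and up-regulations under silencing are informative
(they map to activation and repression respectively).

## Module inference

From the significant calls of each *pair* of perturbed genes (P1, P2):

1. keep pairs where at least one silencing significantly modulates the
   other perturbed gene — the regulating gene takes the upstream role, and
   if both directions are significant both orientations are emitted and
   flagged (a near-feedback situation);
2. intersect the two lists of significantly regulated genes (excluding the
   pair itself) to get common targets;
3. each common target Z yields a component FFL P1→P2, P1→Z, P2→Z. Edge
   sign: down-regulation under silencing = activation, up-regulation =
   repression. Edge phase: any significant stimulation-phase call makes a
   solid, signed, stimulation edge with the earliest such time point
   annotating it (if directions conflict across stimulation time points the
   earliest wins and the conflict is flagged — a screen of this size gives
   no principled way to prefer one, and earliest-first is deterministic);
   wash-out-only regulation gives a dashed edge of unspecified sign, since
   the post-removal dynamics confound the sign interpretation;
4. component FFLs are merged into one multi-output module: 2 + n nodes and
   1 + 2n deduplicated edges for n common targets.

A pair with significant cross-regulation but no common target produces no
module (a module is defined by shared outputs); the bare pair is listed in
the result's `bare_pairs` attribute. The inference is deterministic — pair
and target order follow the gene panel — and is tested for exact agreement
with an independent brute-force triple-scan oracle on hundreds of random
call matrices, so exports (SIF/GraphML/DOT) are byte-identical across runs.

Sign is defined *by the direction rule*, not by computing expression
correlations: in a knockdown design the direction of the target's response
to the silencing is precisely the (signed) influence being measured, and a
correlation across the handful of time points would only add noise to the
same information.

## The synthetic-screen generator

`generate_screen()` emulates the study conditions: a 96-gene card including
3 candidate housekeeping genes, two silenced modulators plus the calibrator
control, time points 0/2/8/12 h with the stimulus removed at 8 h (so 12 h
is wash-out), K = 2 biological replicates, and constant ΔΔCT variance
0.3975 cycles² — the variance family's fitted value at this screen scale.
Planted regulations are ΔΔCT shifts of ±3 cycles at the stimulation time
points by default (|ΔΔCT| = 3 ≈ 8-fold change, a strong but realistic
knockdown response; activation = positive shift). Baseline CT values are
drawn uniformly from 22–30 cycles, the typical mid-dynamic range of
array-card assays.

Noise is calibrated at the ΔΔCT level and decomposed onto the raw CT
values: the control CT of a gene carries noise variance \(v_0/2\) (with
\(v_0\) the model variance at shift 0) and the KD CT carries
\(v(\delta) - v_0/2\), so each cell's replicate ΔΔCT variance equals
\(\alpha + \beta|\delta|^\gamma\) exactly. Housekeeping (hence reference)
CT noise is a separate knob defaulting to 0; putting part of the cell
variance on the reference would couple all genes of a sample and make exact
per-cell calibration impossible when shifts differ across genes. The
generator therefore emulates the *statistical* structure of a screen — not
amplification chemistry, plate effects, or transcription kinetics: planted
effects are constant within their active time points rather than ODE
dynamics, and missingness is absent unless introduced. Passing tests
demonstrate that the pipeline's statistics behave as designed under the
stated noise family; they cannot certify robustness to efficiency
differences between assays or to structured technical artifacts, which the
model does not represent.

Ground truth: the planted effect table is converted to the noiseless call
matrix (every planted shift significant with its implied direction) and the
implied modules are derived from it; the test suite additionally checks the
whole inference path against an independent brute-force enumerator.

## Numerical choices and degenerate inputs

* Nearest-rank percentile (ceiling rank) for the filter: exact,
  platform-independent, no interpolation.
* Bounded LM optimization with `ftol = ptol = 1e-12`, 500 iterations;
  non-convergence returns a flagged object rather than an error so model
  comparison can proceed with the remaining variants.
* Exact fits (WRSS = 0, hence zero standard errors) pass the precision
  screen by convention (CV treated as 0).
* All-equal variances: the filter removes nothing (strict exceedance).
* A zero predicted variance (possible only with a degenerate all-zero fit)
  is a hard error in the z-test rather than a silent division by zero.
* Replicate matching with unequal replicate counts drops the unmatched
  replicates (K decreases); a time-point stratum with no control samples at
  all is a hard pairing error.

## Problem sizes used in the verification suite

The statistical guarantees are verified at the study's own scale: 1000
simulated null screens for the family-wise error rate; 200 Monte-Carlo
repeats of a 96-gene × 3-time-point × 5-experiment grid for variance-model
bias (relative bias of α̂ ≤ 5 %); 200 seeded screens for end-to-end planted
module recovery (≥ 95 % at |ΔΔCT| = 3, constant variance 0.4, K = 2); 500+
random call matrices for brute-force inference equivalence.

## Limitations

* No amplification-efficiency correction or standard-curve quantification:
  the comparative-CT method assumes efficiencies near 1; panels with poor
  assays need upstream correction.
* The variance family is the only error model: no heteroscedastic GLM or
  Bayesian variance estimation.
* Only multi-output FFLs are reconstructed — no bi-fans, cascades, or motif
  enrichment statistics — and edges are influence relations (direct or
  mediated by unmonitored genes), not physical binding claims.
* Bonferroni is the only correction on the default path (an FDR alternative
  would change the meaning of "significant" throughout the module
  definitions).
* With K = 2 the per-cell variance filter is itself noisy; it removes the
  right *fraction* of cells but individual decisions near the threshold are
  unstable. This is inherent to the design it serves.
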