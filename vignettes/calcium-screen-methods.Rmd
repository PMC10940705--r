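---
title: "Methods: kinetic calcium-flux screening analysis with calscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic calcium-flux screening analysis with calscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calscreen)
```

## The problem

Ultra-high-throughput screens of platelet Ca^2+^ signaling record one kinetic
fluorescence trace per well of a 1536-well plate: Calcium-6-loaded platelets
pre-incubated with a compound, then stimulated by robot injection of an
agonist. Two agonists with distinct signaling routes are screened in
parallel — CRP (collagen-related peptide), a GPVI/PLCγ2 agonist producing a
sustained Ca^2+^ rise recorded for ~10 min, and thrombin, a PAR1/4 / PLCβ
agonist producing a transient peak recorded for ~5 min. The analytical goal
is to turn hundreds of thousands of traces into a short, reproducible list
of agonist-*selective* inhibitors while rejecting assay artifacts. This
package implements the full analysis chain — curve profiling, duplicate
reproducibility QC, per-plate normalization and Z-scoring, the
specificity/direction/artifact selection cascade, dose–response
confirmation, and effect-profile comparison — together with a synthetic
plate generator so that every stage is testable against a known ground
truth.

## Seven-parameter curve profiling

Each trace is summarized by seven characteristics:

| Parameter | Meaning | Units |
|---|---|---|
| P1 | baseline immediately before agonist addition (= F₀) | AU |
| P2 | maximal Ca^2+^ increase, P4 − F₀ | AU |
| P3 | slope 1: initial rise rate | AU/s |
| P4 | peak fluorescence after agonist addition | AU |
| P5 | slope 2: post-peak decline (0 when absent) | AU/s |
| P6 | slope 3: late-phase slope, from a per-agonist start time | AU/s |
| P7 | area under the baseline-subtracted curve | AU·s |

All response parameters use F − F₀ rather than F/F₀: the baseline drifts
upward before injection (dye leakage), and subtracting the terminal
pre-injection level is the more robust convention. F₀ = P1 is the median of
the last 5 pre-injection samples (window configurable); a median resists
single-sample spikes and, because only the terminal window is used, is
insensitive to the leakage drift.

Numerical choices that required a decision, and why:

* **Injection localization.** The robot injection produces a sharp
  fluorescence drop (volume addition plus tip shadow). By default the
  layout's configured injection time is trusted; an auto-detection mode
  finds the largest single-step negative deflection within ±10 s and falls
  back to the configured time (flagging low confidence) on traces without a
  convincing drop.
* **Peak (P4).** The peak region is located on a 3-sample moving-average
  smoothed copy; P4 is the raw maximum within half a smoothing window of
  that location. Two refinements matter statistically. First, using the raw
  argmax directly would let noise spikes crown the peak. Second, on
  sustained flat-topped responses the smoothed argmax itself wanders over
  the plateau from well to well, which fattens the tails of the P2/P4
  Z-score distribution across a plate; the implementation therefore anchors
  the location at the *earliest* post-injection sample whose smoothed value
  lies within a noise-scaled tolerance of the smoothed maximum (tolerance
  3·σ̂/√w, with σ̂ estimated robustly from first differences; exactly 0 for
  noise-free traces). With this convention an all-null 1280-well plate
  reproduces the nominal 2Φ(−4) ≈ 1.3 × 10⁻⁴ rate of |Z| > 4 calls for
  every parameter — the property the acceptance suite checks.
* **Slope 1 (P3).** Fitted by least squares over the 10–90% portion of the
  rise, located on the smoothed trace between the post-injection trough and
  the peak. Fitting literally from the minimum sample to the maximum sample
  makes the window endpoints noise-selected order statistics: the fitted
  slope then becomes a discrete mixture across wells (a 3% shift from a
  one-sample change of window is several plate-SDs of P3) and again breaks
  the null Z calibration. Because the endpoints of the fractional-rise
  window always lie on the rise itself, the estimate is insensitive to
  single-sample endpoint jitter, and on any linear rise it equals the true
  slope exactly.
* **Slope 2 (P5).** Least-squares slope over [peak, slope-3 start). The
  decline is "absent" — and P5 exactly 0 — when the baseline-subtracted
  signal never dips below 97% of P2 inside the window. The criterion is
  applied on the response scale (F − F₀), not raw F, so that adding a
  constant to a trace provably leaves P5 unchanged (shift invariance).
* **Slope 3 (P6).** Starts at 650 s (CRP) / 500 s (thrombin) from recording
  start. When the configured start would leave fewer than five trailing
  sample intervals (thrombin's 500 s on a 360 s recording), it falls back
  to 60 s before the trace end, and is never earlier than the peak.
  Whether the published start times count from recording start or from
  injection is not stated anywhere we could verify; both the interpretation
  and the windows are configuration (`profiling_config()`).
* **AUC (P7).** Signed trapezoidal integral of F − F₀ from injection to
  trace end; the small negative area of the injection drop is not floored
  away.

## Duplicate-consistency QC: the difference index

Screens are run in duplicate plates (A and B). For each compound the
pointwise relative difference between the two traces is
r_t = |A_t − B_t| / (max(A,B) − min(A,B)), with the range taken over the
values of *both* signals combined, and the difference index (DI) is the 95th
percentile of {r_t}. Pairs with DI ≤ 30% are consistent; others are excluded
from Z-scoring. Conventions the definition leaves open, pinned here and
configurable: the percentile uses linear interpolation between order
statistics (rank q·(n−1)); the DI is computed on the post-injection segment
only (pre-injection dye-leakage drift differences would otherwise dominate);
traces on different grids are linearly interpolated onto the coarser grid.
DI is symmetric, lies in [0, 1], and is invariant to shifting or scaling
both traces together.

A useful consequence of the definition: a compound pair whose duplicates are
both *flat* (e.g. a failed injection on both replicates) has a combined
range made of noise only, and its DI concentrates around 0.45 — far above
the 30% threshold. Such wells are therefore removed already by the DI
filter, before the dedicated artifact stage ever sees them.

Artifact detectors (thresholds are this package's choices; the published
procedure used visual inspection, which is replaced here by automated
rules):

* **Interference**: a well whose pre-injection median lies more than 6 MADs
  above (autofluorescent) or below (quencher) the distribution of control
  pre-injection medians on the same plate. A zero control MAD is floored at
  1% of the control median.
* **Injection failure**: flagged only when *both* the drop artifact is
  missing (no windowed 3-sample step decrease ≥ 25 AU within ±10 s of the
  injection; a windowed mean is used because a raw single-sample difference
  crosses 25 AU far too often at 2% noise) *and* P2 is below 5% of the
  control median — so a strong inhibitor with an intact artifact is never
  flagged.

## Normalization, Z-scores, and the cascade

Parameters are expressed as percent of the plate's agonist-control mean
(controls = 100%), A/B duplicate percentages are averaged, and Z-scores are
computed per parameter over the compound wells of the plate pair (controls
excluded from the reference distribution). A compound is **active** when at
least one of P2–P7 has |Z| > 4; P1 is excluded from activity because it
flags interference rather than pharmacology. Direction is decided by the
direction parameters (default P2 and P7): inhibitor if all beyond the
threshold are negative, potentiator if all positive, mixed otherwise.

**Robust Z by default.** The classical definition — standard deviations from
the plate mean — is available (`selection_config(z_method = "classic")`),
but it is not the default. A realistic compound plate contains a handful of
strong actives and fluorescence interferers; a single 5× autofluorescent
compound inflates the plate SD so much that an 80%-inhibitor lands at
|Z| ≈ 1–2 and is lost. The default therefore uses median/MAD, which keeps
the nominal null calibration (the MAD estimate adds ~15% to the expected
|Z| > 4 rate at n = 1280, well inside the acceptance band) while being
immune to the outliers the screen exists to find.

Cascade order per agonist, with per-stage retained counts and compound ids
reported:

1. DI-consistent duplicates;
2. active (|Z| > 4);
3. agonist-specific — active for exactly one agonist (a compound measured
   for only one agonist cannot be classified and is treated as
   non-specific, with a warning);
4. inhibitor direction (potentiators and mixed calls removed);
5. artifact rejection (interference or injection failure on either
   duplicate);
6. ADME-Tox flag — an external annotation consumed from a CSV, never
   computed; unknown compounds are retained and logged.

Counts are non-increasing and each stage's ids nest in the previous
stage's; the report embeds the configuration snapshot and its hash, and the
pipeline driver stamps the same hash into every persisted table so outputs
of different configurations cannot be silently mixed.

Note an interaction worth understanding when reading synthetic-screen
reports: an interferer that affects *both* agonists equally is active for
both and therefore exits at the specificity stage, not the artifact stage;
the artifact stage catches interferers whose Z-profile survived specificity
(e.g. duration-dependent dye effects that manifest with one agonist's
recording length only). Likewise, dual flat injection failures exit at the
DI stage as described above. The guarantee that matters — no artifact
compound can reach the final hit list — holds regardless of which stage
removes it, and the acceptance suite asserts exactly that.

## Dose–response confirmation

Re-screened compounds pass a strict >25% inhibition filter
(inhibition = 100 − percent-of-control response). Dose–response series are
fitted by least squares to the four-parameter logistic
R(c) = bottom + (top − bottom)/(1 + (c/IC₅₀)^hill), with IC₅₀ optimized on
the log₁₀ scale, multi-start initialization over an IC₅₀ grid spanning the
observed concentration range, and box constraints (hill ∈ [0.2, 10],
bottom ∈ [−10, 50]%, top ∈ [50, 150]%) that stabilize 4–6-point fits.
Published analyses of this assay type do not state whether the plateaus
were constrained or the fit ran on log dose; the model form and bounds are
exposed in the fit object. Monotone-increasing or flat series are reported
as non-converged with a reason rather than fitted. The fit is invariant to
point order and duplication, and rescaling concentrations by k rescales
IC₅₀ by exactly k.

## Effect-profile comparison

`parameter_correlation()` (Pearson by default, Spearman by flag,
pairwise-complete missing handling), `euclidean_distances()` (optionally on
column-standardized profiles — whether published analyses standardized
first is unstated, so the default standardizes and says so),
`kmeans_profiles()` (50 seeded restarts; the number of clusters is chosen
by mean silhouette width, a choice this package makes explicit because the
published procedure leaves it unexplained), `pca_scores()` (components
sign-fixed so the dominant loading is positive), `univariate_scale()`
(per-column min–max scaling to [0, 10]; constant columns map to 0 with a
warning) and `subtraction_matrix()` (label-aligned treated − control
differences, negative = decrease) operate on labeled matrices; matrices are
the contract, figures a courtesy. `log2_effect_matrix()` produces the
log₂(percent-of-control/100) matrices used for inhibitor-effect heatmaps,
with non-positive percentages carried as missing.

## The synthetic world

`generate_screen()` produces duplicate A/B 1536-well plate pairs for both
agonists with the standard control arrangement (192 agonist-control wells,
64 buffer-control wells, up to 1280 compound wells) and a known ground
truth. Traces are phenomenological piecewise curves — no receptor kinetics
or store-release ODEs: baseline with dye-leakage drift, a sharp injection
drop, a short receptor latency, a linear rise, then a transient decay
(thrombin) or a sustained slowly declining plateau (CRP). Defaults, chosen
once as a realistic stated world:

| Quantity | Default | Rationale |
|---|---|---|
| sample interval | 2 s | typical kinetic plate-reader cadence |
| injection time | 60 s | 1 min baseline recording |
| recording length | 660 s CRP / 360 s thrombin | 10 vs 5 min post-injection windows |
| baseline | 100 AU; leakage drift 0.05 AU/s | drift visible but small against responses |
| injection drop | 40 AU; latency 4 s | deep enough to be detectable at the working noise |
| peak | 500 AU (P2 ≈ 400 AU) | strong control response |
| rise rate | 4 AU/s CRP / 13 AU/s thrombin | sustained vs fast transient kinetics |
| post-peak | −0.3 AU/s plateau CRP / −1.2 AU/s decay thrombin | sustained vs return toward baseline |
| noise | 8 AU i.i.d. Gaussian per sample | 2% of the control maximal increase |

Planted effects scale the post-injection deviation from baseline
(inhibitor/potentiator, so peak-minus-baseline scales exactly by the
magnitude), scale the whole trace (autofluorescent/quencher), or replace
the trace by drifting baseline with no drop (injection failure), each with
an agonist selectivity. The default mixture plants 5% CRP-only and 5%
thrombin-only inhibitors at magnitude 0.2, plus dual inhibitors,
potentiators, interferers and per-agonist injection failures (see
`default_effect_spec()`); single-agonist quenchers emulate
duration-dependent dye interference and exercise the artifact stage of the
cascade. Randomness is fully reproducible: one global seed, with per-well
substreams derived deterministically from (plate, well) so results do not
depend on generation order.

What the generator deliberately does **not** emulate — and hence what a
green test does not establish: autocorrelated or multiplicative noise,
plate-position (edge/row) effects, liquid-handling gradients, compound
carry-over, donor-to-donor platelet variability, and partially effective
injections. Published quantitative noise and drift magnitudes are not
available; the defaults above are calibrated only so that planted-effect
recovery is a meaningful test. Exact reproduction of any published
full-screen stage counts additionally depends on conventions no
publication states (which parameters drove the active call, how duplicates
were merged), which is why the binding validation here is the synthetic
property suite, with real screening exports consumed through the same
importers when available.

## Known limitations

* The interference and injection-failure thresholds (6 MAD, 25 AU, 5%) are
  this package's operationalization of a visual-inspection step; they are
  exposed in `qc_config()` and logged, but not validated against manually
  annotated real traces.
* Compounds measured with only one agonist cannot enter the specificity
  stage and are conservatively treated as non-specific.
* The 4PL fit is unweighted (replicate SDs are unavailable at screen
  scale); confidence intervals for IC₅₀ are not produced.
* DI-based filtering removes compounds whose duplicates are both flat —
  including genuine full inhibitors at very high magnitude; this mirrors
  the stringency/false-negative trade-off inherent to the published
  filtering order (DI before Z).
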