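---
title: "Methods: movement-state band-power analysis of LFPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement-state band-power analysis of LFPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lfpband)
```

## The scientific question

In hemiparkinsonian rodent models (unilateral 6-OHDA lesion of the
substantia nigra pars compacta), dopamine depletion reorganises oscillatory
activity throughout the cortico–basal-ganglia circuit. A sensitive way to
expose this is not absolute band power but its *transient, movement-related
change*: the difference between the band power recorded while the animal
walks and while it rests, taken per subject, per recording site and per
frequency band. `lfpband` implements that analysis end to end, for
five-channel local field potential (LFP) recordings from M1, CPu, STN, SNc
and PPN, together with the behavioral and histological endpoints that
typically accompany such a study.

## Pipeline

For every recording the stages run in a fixed order — filter the full
trace, then select a segment, then epoch it:

1. **Conditioning.** Zero-phase band-pass, 0.5–80 Hz, realised as a
   4th-order Butterworth high-pass/low-pass cascade. The two-pass
   (squared-magnitude) response is applied in the frequency domain after
   extending the signal at both ends by Burg autoregressive extrapolation.
   The cascade avoids the numerical fragility of an order-8 band-pass
   transfer function whose lower corner sits at 0.001 of Nyquist, and the
   AR padding matters because the high-pass transient lasts several
   seconds: with naive (reflection or zero) padding, the warm-up blip lands
   exactly on the earliest windows, which is where resting-state segments
   are typically taken. For marginally stable AR fits (very slow signals)
   the padding falls back to bounded odd reflection.
2. **Segment selection.** The earliest artifact-free 10 s window inside
   each annotated state interval. The default artifact rule flags samples
   deviating from the state-interval median by more than 6 robust standard
   deviations (scaled MAD); an absolute-amplitude rule and a pass-through
   rule are available. The earliest-window policy makes runs reproducible
   and favours the start of each behavioral state.
3. **Epoching.** The 10 s segment is cut into ten non-overlapping 1 s
   epochs; a trailing partial epoch would be dropped with a warning.
4. **Spectra.** Welch's estimator with the 1 s epochs as its segments:
   periodic Hann window, one-sided density normalisation
   (`sum(psd) * df` = windowed variance), 1 Hz resolution. A unit-variance
   white signal has density `2/fs`; a sinusoid of amplitude A integrates to
   `A^2/2` around its peak.
5. **Band integration.** Rectangle-rule integrals over delta [1, 4),
   theta [4, 8), alpha [8, 21), beta [21, 32) and gamma [32, 100) Hz. Bands
   are half-open so shared printed edges are counted once and the five
   bands tile [1, 100) exactly; the non-standard alpha/beta split is kept
   as the analysis convention of this literature. Gamma deliberately
   extends to 100 Hz although the conditioning passband ends at 80 Hz —
   the 80–100 Hz tail carries whatever passes the filter skirt, which is
   recorded in the run manifest.
6. **Difference statistic.** Per subject × region × band,
   `diff = walk − rest` on absolute power (µV²). Spectra are subtracted
   directly, not in dB.

## The split-plot ANOVA

Each band's difference table is analysed with a two-way mixed
repeated-measures (split-plot) design: `group` (sham vs lesion) between
subjects, `region` (5 channels) within subjects. With n subjects per group
the degrees of freedom are (1, 2n−2) for group and (4, 4(2n−2)) for the
within effects — (1, 18) and (4, 72) at the reference n = 10. The group
effect is tested against subjects-within-groups; region and group×region
against the region×subjects-within-groups residual.

Sphericity of the within-subject covariance is tested with Mauchly's W on
the pooled within-group covariance (df = N − g, the standard mixed-design
convention); when Mauchly's p < 0.05 the Greenhouse–Geisser correction is
applied: ε = (Σλ)² / ((k−1) Σλ²) over the eigenvalues of the doubly-centred
covariance, bounded in [1/(k−1), 1], multiplying both within-effect dfs for
the reported p (F itself is unchanged). A numerical remark: shrinking the
dfs is not literally monotone in p when F < 1 — the reported p can then
drop slightly below the uncorrected one. This has no inferential
consequence (such effects are far from significance) and matches standard
software, which applies the correction unclamped.

Effect sizes are partial η² = F·df1/(F·df1 + df2), the identity that also
lets published tables be checked from their printed F and dfs alone.

Post hoc comparisons are classical Fisher LSD: all pairwise contrasts of a
factor's marginal means using that stratum's pooled error mean square and
df, two-sided, unadjusted, and gated by the omnibus effect. Channel
comparisons pool across groups. For reporting, significant pairs are
compressed into ordering strings such as `PPN/SNc/STN > M1`; labels joined
by `/` are mutually non-significant, and statements with identical left
clusters merge their right sides under the same rule. The rendered report
table prints LSD entries whenever the omnibus effect is at least marginally
significant (p < 0.1), mirroring the convention of published tables that
annotate marginal effects; `NA` marks the rest.

## The endpoint test cascade

Behavioral and histological endpoints are compared between groups with an
assumption-driven cascade: Shapiro–Wilk normality per group and
(mean-centred) Levene homogeneity at α = 0.05; on violation the data are
re-tested after log (positive data only) and then square-root
(non-negative data only) transforms; if some scale satisfies the
assumptions a pooled-variance independent t test is run on that scale,
otherwise a Mann–Whitney U test on the original data. The U test reports
the conventional continuity- and tie-corrected normal Z alongside an exact
p (full enumeration) whenever the samples are small and untied — for tiny
groups the normal approximation is visibly off (two-sided p 0.081 instead
of the exact 0.1 at complete separation with n = 3/3), so the exact value
is the one reported. Significance classes follow p < 0.05 (significant) and
0.05 ≤ p < 0.1 (marginal).

Aggregation: multi-trial endpoints (rotarod, pole) enter as per-subject
trial means — the simplest defensible rule where the assay convention is
unstated. The cylinder asymmetry ratio is
`(inj − non-inj) / (inj + non-inj + both) × 100`; gait support percentages
are per-class frame fractions (diagonal, three-limb, other; "other" is
carried in summaries but not tested). TH+ histology uses per-slice density
`count / area` (cells/mm²), averaged over the three slices of a subject and
hemisphere, with percent loss `(1 − lesion/sham) × 100` relative to the
sham group mean.

## The synthetic generator and what it does (not) emulate

`generate_lfp_dataset()` simulates the full recording design: 2 groups ×
n subjects × 5 regions, one contiguous resting and one walking phase at
1000 Hz. Each channel-state trace is

* a 1/f^β background (β = 1, RMS 12 µV by default), synthesised with
  deterministic spectral amplitudes and random phases (the surrogate-data
  construction). Every realization then has exactly the nominal spectrum
  and RMS; band-power estimates fluctuate only through windowing
  (about 5–6% CV for a 68-bin × 10-epoch gamma integral). An empirically
  renormalised synthesis was rejected because the renormalisation factor —
  dominated by the few lowest-frequency bins of a 1/f spectrum — imposes an
  artifactual common fluctuation on all bands;
* plus, per band, a random-phase sinusoid with ±0.5 Hz per-second frequency
  jitter and continuous phase, whose RMS is set by the band-effect table
  times a per-subject lognormal multiplier (σ = 0.2). Injected band power
  is therefore known exactly: RMS² × multiplier².

The bundled demonstration effects place walk-state oscillations at 2.5, 6,
12, 26 and 50 Hz (carriers mid-band; gamma at 50 Hz so the filter skirt
does not eat injected power) and encode the lesion phenotype in gamma: an
increase in M1, STN, SNc and PPN but not CPu, with regional magnitudes
chosen so that pooled channel means rank M1 lowest, CPu intermediate and
PPN/SNc/STN highest, the group contrast is ≈1.45 between-subject SD
(≈87% power at n = 10), and the channel gaps sit at ≈1.5–3 pooled standard
errors — large enough for `PPN/SNc/STN > M1` to dominate the LSD orderings,
small enough that CPu usually separates from neither side. Because the
1/f background dominates the low bands at these amplitudes, delta–beta
group effects are weaker and delta is usually non-significant in the demo —
a realistic property of absolute-power analyses of low frequencies.

What the generator does **not** emulate: non-stationarity within states,
movement artifacts with realistic morphology (artifacts are tested with
injected spikes), volume conduction or inter-regional coherence, spike
contamination, and any biophysical circuit structure. Passing recovery
tests therefore demonstrates that the *pipeline* recovers known injected
structure under realistic noise — not that real 6-OHDA recordings would
show these exact values.

Table-level companions exist for calibration studies:
`simulate_diff_table()` draws difference tables directly from the
generator's statistical model (group/region shifts + normal subject
intercept + exchangeable residual), which is what the type-I-error
calibration of `mixed_anova()` uses (1000 null tables at n = 10/group).

## Problem sizes and numerical choices

* Reference study: 2 × 10 subjects, 5 regions, 5 min per state at 1000 Hz
  (the bundled `demo_config()`); it runs end to end in about a minute on
  one CPU. Recovery simulations use 12 s states: since exactly one 10 s
  segment per state is analysed, the band-power statistics are unchanged
  while 50 replicates stay cheap.
* Exact RMS scaling in both generators (requested RMS is met to machine
  precision); `rms = 0` yields exact zero signals.
* All generator entry points take a `seed` and restore the caller's RNG
  state; identical seeds give byte-identical outputs.
* Degenerate inputs fail loudly: unbalanced or incomplete ANOVA designs,
  missing rest/walk partners, all-zero cylinder counts, constant samples in
  Shapiro–Wilk, bands outside the spectral grid, windows longer than the
  state interval.
* Report rounding is three decimals, half away from zero.

## Known limitations

* Channel p values under a Greenhouse–Geisser correction depend on the
  realised ε; published tables that omit ε cannot be reproduced row-for-row
  without raw data, and no attempt is made to do so — analytic identities
  (η², between-subject p) and design-level recovery are the validation
  surface instead.
* The delimited-matrix + JSON-sidecar interchange format is the supported
  reader/writer; there is no EDF I/O.
* The Mauchly p value uses the standard chi-square approximation; it can
  differ in the third decimal from implementations carrying higher-order
  series terms.
* Filtering near recording boundaries is as good as the AR extrapolation:
  the lowest band can still carry a small edge bias in the first seconds
  of a recording.
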