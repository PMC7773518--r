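---
title: "Methods: COP balance metrics and between-device agreement for the SOT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COP balance metrics and between-device agreement for the SOT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sotagree)
```

## The problem

The sensory organization test (SOT) is the standard clinical protocol for
isolating the visual, somatosensory and vestibular contributions to standing
balance.  Its six conditions progressively remove or corrupt vision and
surface proprioception; a computerized dynamic posturography system reports,
per condition, an *equilibrium index* (EI) on a 0–100 scale.  A portable
alternative — a consumer head-mounted display reproducing the six sensory
manipulations plus a force plate under the feet — records a center-of-pressure
(COP) trajectory instead of a proprietary score.  Validating the alternative
requires (a) turning COP traces into a comparable *estimated equilibrium
index* (eEI) and companion sway metrics, and (b) quantifying per-condition
agreement between the two devices.  `sotagree` implements both halves as a
tested pipeline, together with a synthetic paired-session generator so every
stage can be exercised without human data.

## Scoring model

The eEI converts anterior–posterior (AP) COP excursion into sway angles over
an estimated centre-of-gravity (COG) height $h = 0.56 \cdot \text{stature}$:

$$\theta_{ant} = \sin^{-1}\!\frac{\max(x_{AP})}{h}, \qquad
  \theta_{post} = \sin^{-1}\!\frac{|\min(x_{AP})|}{h},$$

$$\mathrm{eEI} = \mathrm{clamp}\!\left(100\,
  \Bigl(1 - \frac{\theta_{ant}+\theta_{post}}{12.5^\circ}\Bigr),\; 0,\; 100\right).$$

No sway scores 100; combined sway at or beyond the theoretical 12.5° limit
scores 0.  Both constants are exposed in `ei_params()`.  Peak (rather than
per-sample) excursions are used because the clinical score is a single
per-trial number built from the extreme forward and backward sway.  Whether
the clinical scale can go negative is not observable from its outputs; we
clamp at 0, matching the stated floor.  An AP excursion reaching $h$ makes
the inverse sine undefined and raises a domain error rather than returning a
fabricated angle.

The companion metrics are the standard stabilometric trio:

* **95% ellipse area** $= \pi\,\chi^2_{0.95}(2)\,\sqrt{\det S}$ with $S$ the
  2×2 AP/ML sample covariance ($n-1$ denominator).  We use the
  $\chi^2$-quantile *prediction* ellipse with the fixed constant
  $\chi^2_{0.95}(2) \approx 5.991$ (configurable via `conf`), not the
  F-based small-sample correction — the convention most common in
  posturography software.
* **Path length** $= \sum_i \sqrt{\Delta x_{AP,i}^2 + \Delta x_{ML,i}^2}$.
* **AP DFA $\alpha$** — detrended fluctuation analysis of the AP channel:
  integrate the mean-removed series, partition into non-overlapping boxes
  anchored at the series start, remove an order-1 polynomial per box, and
  regress $\log F(n)$ on $\log n$.  Defaults (`dfa_config()`): box sizes
  log-spaced from 4 samples to a quarter of the series, 12 sizes, linear
  detrending — ordinary stabilogram practice.  White noise yields
  $\alpha \approx 0.5$ and integrated noise $\alpha \approx 1.5$; these two
  anchors are the implementation's sanity checks in the test suite.
  No installed R package provides DFA, so it is implemented here.

## Preprocessing

Traces are conditioned by linear detrending per axis followed by a centred
moving-average filter (`preprocess_config()`, default window 20 ms).  At the
50 Hz sampling rate of the study design a 20-ms window spans a single sample,
i.e. the filter is the identity; the window is kept configurable because
force plates commonly stream at higher internal rates where the same setting
is a real smoother.  Edge samples use shrunken windows so no data are
invented at trial boundaries, and the order is fixed as detrend-then-filter.

## Agreement statistics

Per condition, the paired (EI, eEI) table feeds:

* **ICC, two-way, single measure** from the ANOVA mean squares of the n×2
  table — consistency $(MS_R - MS_E)/(MS_R + MS_E)$ and absolute agreement
  $(MS_R - MS_E)/(MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E))$.  These are the
  ICC(3,1)/ICC(2,1) forms of the Koo–Li framework.  The published
  interpretation bands overlap as printed ("moderate 0.5–0.75" vs "good
  0.5–0.9"); we resolve the overlap to the standard Koo–Li bands
  (good = 0.75–0.9).
* **Pearson r** with the two-sided p from the t-distribution on $n-2$ df
  (via `stats::cor.test`); correlation labels are applied to $|r|$ so that,
  e.g., $r = -0.506$ is "moderate".
* **Bland–Altman**: differences $d_i = \mathrm{eEI}_i - \mathrm{EI}_i$,
  mean difference and limits $\bar d \pm 1.96\,s_d$ (multiplier
  configurable).

## Pipeline rules

`run_sot_pipeline()` applies the study's reduction rules:

1. **Final trial only.**  The first trial per condition and device is a
   familiarization run; the record with the highest trial index is analyzed.
2. **Single-pass 3-SD paired exclusion.**  Per condition and device, scores
   beyond 3 SD of that vector's mean are flagged; a flag on either device
   removes the participant's whole pair for that condition.  Means and SDs
   come from the unfiltered vectors and are not re-estimated (iterative
   re-screening would not reproduce a one-shot removal).  The screen is
   applied to the primary scores (EI/eEI) only; screening every metric
   would cascade removals beyond the described procedure.  Note that with
   very few pairs a single outlier can never exceed 3 SD of its own vector
   (the standardized deviation is bounded by $(n-1)/\sqrt{n}$), so the
   screen is inert below $n = 11$ by arithmetic, and skipped below $n = 3$
   by rule.
3. **Pairing by condition code.**  The six SOT codes are shared by both
   devices (`sot_conditions()` records the sensory-quality taxonomy); the
   two head-tracking-only VR environments (`VRX1`, `VRX2`) complete the
   28-trial session but have no clinical counterpart and are ignored.
4. **Graceful degradation.**  A condition with fewer than 3 retained pairs
   is reported with missing statistics and a warning; a batch run never
   aborts on one bad condition.

Whether the historical screen pooled devices per condition is not stated
anywhere observable; we screen per device, which is the stricter reading and
keeps the two flags interpretable in the exclusion log.

## The synthetic generator

`simulate_study()` emulates the full design: 20 participants (7 male /
13 female by default; heights drawn per sex from N(1.79, 0.079²) and
N(1.66, 0.072²) m — the published per-sex means with standard errors scaled
back to SDs), six conditions × two devices × two trials of 20 s at 50 Hz,
plus the two unmatched VR environments, i.e. 28 trials per participant.

Sway traces are first-order autoregressive (mean-reverting) processes with
a 1-s time constant, started from their stationary distribution — bounded by
construction, so the inverse-sine model stays defined.  A pure random walk
was rejected because 20-s walks drift without bound.

Agreement is planted through a single latent correlation $\rho$: per
participant and condition a stability latent $z \sim N(0,1)$ drives the
Equitest score linearly, and $w = \rho z + \sqrt{1-\rho^2}\,z'$ drives the
VR sway angle log-normally,
$\theta = \theta_c \exp(-s\,w + \varepsilon)$, with trial-level noises on
both channels.  Each VR trace's detrended AP channel is rescaled so its
combined sway angle *exactly* realizes the trial's draw — the generator
plants scores, and the pipeline must re-derive them from raw samples.  The
condition scale $\theta_c$ is derived from the per-condition sway scale
$\sigma_c$ (metres) through a nominal peak-to-RMS factor, so raising
$\sigma_c$ strictly lowers the expected score.  Because one channel is
linear and the other log-normal in jointly Gaussian latents, all second
moments are available in closed form; `sim_expected_agreement()` returns the
implied per-condition population ICCs and Pearson r, and every simulated
study carries them in its truth record (`sim_truth()`).  Boundary clamping
of the 0–100 scale is rare under the default scales and is ignored by the
closed forms.

Default sway scales (6.2–17.5 mm) were chosen once to put expected scores in
a realistic 40–95 band that declines with condition difficulty — no
per-condition score distributions exist to emulate, so this is an explicit
modelling choice.  The default $\rho = 0.75$ yields moderate planted ICCs
(≈0.54–0.66), the regime the method-comparison question cares about.

What the generator does *not* emulate: intermittent postural control,
rambling–trembling structure, learning across trials, or distinct dynamics
per VR tracking mode.  Passing recovery tests therefore demonstrates that
the pipeline measures what was planted under a plausible sway model — not
that any particular device pair agrees on real humans.

## Numerical choices and problem sizes

* Uniform sampling is enforced with a 1 µs tolerance on the time step;
  trace CSVs round-trip at better than 1e-9.
* The angle-realization root solve uses `uniroot` at tolerance 1e-12 on a
  bracketed monotone function.
* Per-trial simulation substreams are derived deterministically from the
  study seed (a linear-congruential fold kept below $2^{31}$), so any trial
  is reproducible in isolation.
* Test problem sizes: oracle-equivalence checks use ≤10-row tables;
  the DFA anchors use 50 series of length 2000; ellipse calibration uses
  one 10^5-sample trace; parameter recovery uses 50 replicate studies at
  20 participants and 25 at 200, with recovery bands of ±0.15 and ±0.05
  around the closed-form target.  These sizes make the whole suite run in
  minutes while keeping Monte-Carlo error well inside each band.

## Worked call

```{r example, eval = FALSE}
cfg <- sim_config(n_participants = 20, rho = 0.75)
study <- simulate_study(cfg, seed = 11)
res <- run_sot_pipeline(study)

res$conditions          # per-condition ICCs, Pearson, Bland-Altman
tidy(res)               # long correlation table (EI vs each COP metric)
glance(res)             # one-row summary
autoplot(res, "bland_altman")
sim_truth(study)$conditions$icc_consistency   # planted targets
```

## Known limitations

* The ICC is the two-device, single-measure form; multi-rater designs and
  ICC confidence intervals are out of scope.
* The eEI's COG-height fraction (0.56) is an anthropometric convention, not
  a per-participant measurement; systematic deviations fold directly into
  the sway angle.
* The ellipse and DFA conventions above are declared, not uniquely implied
  by the clinical score they accompany; both are configurable.
* File I/O covers the package's documented CSV/YAML dialect only —
  proprietary force-plate formats (including C3D) are not read.
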