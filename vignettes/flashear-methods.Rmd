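---
title: "Models and methods behind flashear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flashear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashear)
library(dplyr)
```

`flashear` implements the quantitative chain of a proton-FLASH skin study on
the mouse-ear model: pulsed-beam dosimetry, the irradiated-blood-volume
model, longitudinal inflammation analysis, and ΔΔCt qPCR fold changes, plus
synthetic-data generators that make every stage testable against known
ground truth. This vignette describes the models, their assumptions, and the
design choices made where the underlying procedures leave room.

## Pulsed-beam dosimetry

A thin target (a mouse ear is ~0.23 mm of tissue; a 20 MeV proton traverses
it with nearly constant stopping power) absorbs dose at a rate set by the
proton current $I$, the linear energy transfer $L$, the field area $A$ and
the medium density $\rho$:

$$\dot D \;=\; \frac{I/e \,\cdot\, L}{A\,\rho},$$

with $I/e$ the proton rate. `dose_rate_from_current()` centralises every
unit conversion (nA, keV/µm, mm², g/cm³ → Gy/s); the result is exactly
linear in $I$ and $L$ and inverse-linear in $A$ and $\rho$. At the study's
settings (15 nA, 2.6 keV/µm, 42 mm², unit density) it gives
`r round(dose_rate_from_current(15, 2.6, 42), 1)` Gy/s, within 1 % of the
nominal 930 Gy/s. The density is not stated by the experiment and defaults
to water-equivalent 1 g/cm³; it is an explicit parameter.

Dose-rate modes are produced by a chopper passing every $2^k$-th pulse of a
5 MHz train: the pulse-to-pulse distance is $2^k / 5\,\mathrm{MHz}$
(`chopper_period()`), the duty cycle is pulse width over pulse period, and
the mean dose rate is the in-pulse (peak) rate times the duty cycle
(`mean_dose_rate()`). The three default configurations in `flash_beams()`
are: continuous 15 nA (930 Gy/s); 128 ns / 12.8 µs chopping of the same
current (duty 1/100, 9.3 Gy/s); and 0.4 nA chopped at 128 ns / 51.2 µs
(duty 1/400, 0.06 Gy/s). For the slow mode we use the 51.2 µs period implied
by partition $2^8$ of the 5 MHz train and consistent with the 400-fold
peak-to-mean current ratio (0.4 nA peak, 0.001 nA mean); the period remains
a free parameter of `beam_config()`. Durations for a prescribed dose follow as
dose over mean rate; reported dose rates carry two significant digits, and
durations quoted at reported precision are computed from the
reported-precision rates, which is how the printed 0.035 s / 3.55 s /
9.17 min arise for 33 Gy.

The slow mode's *peak* dose rate is reported upstream as 24 Gy/s while
linear current scaling gives 24.8 Gy/s; because the provenance of that
rounding is unknown we exclude this one cell from reproduction checks.

## Irradiated blood volume

The blood exposed during one irradiation splits into a **static** part — the
blood standing in the vessels of the field — and a **flow** part — the blood
exchanged through the veins entering the field while the beam is on:

$$V_\mathrm{static} = \sum_{c \in \{\text{thick, middle, thin}\}} \frac{\pi d_c^2}{4} \sum_{i \in c} l_i,
\qquad
V_\mathrm{flow} = \sum_{j=1}^{m} \frac{\pi d_j^2}{4}\, v\, t,
\qquad
V_\mathrm{irr} = V_\mathrm{static} + V_\mathrm{flow}.$$

Traced vessels are treated as cylinders in three by-eye thickness classes
with default diameters 0.09 / 0.05 / 0.04 mm (configurable, with optional
per-segment overrides); lengths come from segmented-line traces via
`polyline_lengths()`. Entry vessels are assumed to be veins (larger than the
arteries), flowing at $v \approx 2$ mm/s in the Balb/c ear; only thick and
middle-thick vessels count as entry veins (thin ones trigger a warning, not
an error). Volumes are computed in mm³ and reported in µl (1:1); rounding to
reported precision happens only at the reporting layer.

The mean dose to the exposed blood uses the residence-time dilution rule

$$D_\mathrm{blood} = D \cdot \frac{V_\mathrm{static}}{V_\mathrm{irr}},$$

which equals the prescribed dose when nothing flows and reproduces the
0.24 Gy endpoint of the slow mode (33 Gy × 0.20/27). For the intermediate
9.3 Gy/s mode a half-irradiation argument has also been quoted upstream
(17 Gy); the dilution formula gives 17.8 Gy. We implement the single general
rule rather than a mode-specific argument, and document the difference here.

The number and calibre of entry veins are not published. The packaged
synthetic trace uses four thick (0.09 mm) entry veins and per-class lengths
(12 / 35 / 43.72 mm) calibrated so $V_\mathrm{static} = 0.20$ µl — this
reproduces all three published irradiated volumes within their printed
uncertainties (0.20 / 0.37 / 27 µl for 0.035 s / 3.55 s / 550 s), but it is
a fixture, not ground truth. Replicate traces are combined by
`replicate_summary()`, which reports across-replicate mean, SD and SEM
(missing, never zero, for single replicates) and a first-order (delta
method) SD for derived ratios; a seeded Monte-Carlo check in the test suite
confirms the delta-method SD within 5 %. Because it is ambiguous whether
published error bars are SDs or SEMs, both are reported.

## Longitudinal swelling and inflammation scores

Ear swelling of mouse $i$ at time $t$ is sham-referenced thickness,
$ES_i(t) = ET_i(t) - \overline{ET}_\mathrm{sham}(t)$. Mice are monitored
every 2–7 days on individually varying schedules, so two alignment rules are
needed; the procedure's source is silent on both:

* the sham mean is evaluated exactly on days with sham observations and
  linearly interpolated in between (clamped at the range ends, never
  extrapolating a trend) — this preserves the identity that the sham group's
  own mean swelling is exactly zero on every sham-observed day;
* group curves (`group_curve()`) interpolate each mouse's series onto a
  common day grid before averaging, so every mouse contributes to every
  grid day (`align = "observed"` restricts to mice actually measured that
  day; SEM is reported missing for $n = 1$).

The inflammation score is the sum of ordinal erythema
(0 / 0.5 / 1.5 / 3) and desquamation (0 / 1 / 2 / 3) grades, range 0–6,
with case-insensitive label matching and numeric passthrough.

`peak_reaction()` takes each group's maximum of the mean curve (earliest day
on ties; a day window is available). For percent reductions we compare each
group at *its own* peak by default — the alternative, evaluating all groups
at the reference group's peak day, is available via
`peak_mode = "common_day"` — because the published comparisons are of
"maximum reaction" values. The reduction and its uncertainty use first-order
propagation,

$$R = 100\left(1 - \frac{m_t}{m_r}\right), \qquad
\sigma_R = 100\sqrt{\left(\frac{\sigma_t}{m_r}\right)^2 +
\left(\frac{m_t \sigma_r}{m_r^2}\right)^2},$$

which is scale-invariant and matches a Monte-Carlo check within 5 %. The
published reduction uncertainties are not exactly recoverable from the
published peak values by this (or any standard) propagation; we implement
the standard rule and note the discrepancy. Group differences use a
two-sided pooled-variance Student t-test on per-mouse values interpolated at
the group's peak day (Welch by flag); when both groups have zero variance —
possible for the deterministic ordinal scores of synthetic cohorts — the
limiting statistic is reported with a warning instead of an error. P-values
are reported raw, with no multiple-testing correction, matching the original
analysis.

## ΔΔCt fold changes

For each sample, target Ct is the arithmetic mean of up to three well
replicates (undetermined wells are dropped with a warning, never imputed; an
optional spread QC beyond 0.5 cycles only warns). Normalization subtracts
the housekeeping Ct of the same sample; with both B2M and GAPDH assayed the
default normalizer is the arithmetic mean of the two housekeeping Ct means
(equivalent to geometric-mean expression normalization), with
`hk_mode = "single"` selectable since the original normalization to "the
housekeeping gene" (singular) is ambiguous. The sham reference ΔCt is the
mean over sham samples of the same gene and day (no day pooling). Then

$$\Delta\Delta C_t = \Delta C_t - \overline{\Delta C_t}^{\,\mathrm{sham}},
\qquad FC = 2^{-\Delta\Delta C_t}, \qquad \log_2 FC = -\Delta\Delta C_t,$$

exact identities that the tests assert symbolically. Summaries are
descriptive mean ± SD per gene/group/day (no inferential testing, mirroring
the original presentation); adding a constant to every Ct of a sample leaves
ΔΔCt unchanged (housekeeping invariance), and the sham group's own mean ΔΔCt
is zero by construction. No amplification-efficiency correction is applied.

## Synthetic-data generators

The generators emulate the study's design: group sizes 7/7/9/3/7/9 plus 7
sham animals; measurement days drawn every 2–7 days over 180 days; ear
thickness $ET = 230\ \mu m + A_g\, g(t) + \mathcal N(0, 25\ \mu m)$. The
response shape $g$ is a gamma kernel normalized to 1 at its peak — onset
day 12, peak day 23, effectively zero again past day 60 — because only these
landmarks, not a functional form, are known. The 33 Gy amplitudes are
$A_\mathrm{Conv} = 155$ µm with FLASH amplitudes 93 µm and 66.65 µm,
encoding true reductions of exactly 40 % and 57 %; the 23 Gy amplitudes
(49/40/30 µm) match the published peak magnitudes. The baseline 230 µm is an
assumed constant — absolute thickness never enters the analysis (only
sham-referenced differences do), so the choice is inert. Ordinal grades are
emitted by thresholding the *noiseless* swelling (erythema at 40/120/250 µm,
desquamation at 100/160/250 µm, placing the strongest group's peak score
near 2.5 and the 23 Gy groups below 1); a consequence is that synthetic
scores have no within-group variance at a common day, which the t-test
handles via its degenerate-limit branch.

qPCR plates draw a per-sample housekeeping level
$\mathcal N(\mathrm{base}, 0.4)$ cycles, add gene-specific baseline ΔCt
values, subtract the injected $\log_2 FC$ (zero by default, mirroring the
null cytokine finding), and add $\mathcal N(0, 0.2)$-cycle replicate noise
per well. Vessel traces are random smooth walks placed inside the
6.5 × 6.5 mm field whose step lengths sum exactly to the requested per-class
totals, so the analytic static volume of the generated trace is known in
closed form and round-trips exactly through `polyline_lengths()`.

Each generator draws from its own sub-seed derived from the master seed by a
fixed label, so adding one generator to a workflow never perturbs another's
output, and all outputs are byte-identical under a fixed seed.

What the generators deliberately do not model: per-mouse response
heterogeneity (amplitudes are group constants), dose-delivery scatter
between animals, left-ear measurements, scoring-observer noise, and any
biophysics of the FLASH effect itself. Passing recovery tests therefore
shows that the *estimators* are unbiased and honestly calibrated under the
assumed noise model — not that the biological conclusions are reproduced.

## Numerical choices and problem sizes

* Comparisons against published numbers round half-away-from-zero to the
  printed number of decimals (`round_printed()`, `round_half_up()`), since
  fixed-precision tables are the only available reference.
* Peak ties break to the earliest day; interpolation is linear and clamped;
  SEM/SD with $n < 2$ is missing, never zero.
* The test suite validates `static_volume()` against a Monte-Carlo
  voxelization of the same cylinders (20 random traces, $10^5$ points per
  segment, 1 % tolerance), reduction recovery over 200 replicate cohorts at
  the study's group sizes (coverage of the injected truth within
  $2\sigma$ in ≥ 90 % of replicates), qPCR recovery bias over 100 plates
  (< 0.05 log2 units), and the t-test's type-I error over $10^4$ null
  simulations (0.05 ± 0.01). These sizes keep the full suite around a
  minute on one core while leaving the Monte-Carlo error well below each
  tolerance.
* The acceptance script averages the reduction estimator over 25 replicate
  cohorts: a single cohort at these group sizes estimates the reduction
  with a sampling SD of 6–9 percentage points, so the replicate mean is the
  meaningful summary of what the estimator recovers.

## Known limitations

* The blood-volume model ignores joint overlap where traced segments meet,
  vessel taper, pulsatile and arterial flow, and any lymphocyte-kill
  modelling beyond mean-dose dilution; entry-vein count and calibre are a
  calibrated fixture.
* Day alignment by linear interpolation slightly flattens sharp peaks for
  sparsely monitored mice; the peak-window option mitigates this.
* The reduction estimator inherits a small downward bias from taking the
  maximum of a noisy mean curve (the reference peak is inflated slightly
  more than the test peaks are); at the study's group sizes this is within
  one sampling SD.
* No proton transport, LET-depth or field-homogeneity modelling; no film
  dosimetry; no image segmentation — vessel traces are consumed, not
  produced.
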