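# flashear

Quantitative analysis for preclinical proton-FLASH studies on the mouse-ear
model. The FLASH effect — sparing of healthy tissue at ultra-high dose rates
(> 40 Gy/s) at equal total dose — is routinely assayed in the mouse ear,
where skin reactions are scored for months and, because the ear is
quasi-two-dimensional, the irradiated blood volume can be estimated from
trans-illuminated vessel traces. `flashear` packages the full analysis
chain of such a study for radiobiologists and beamline physicists:

* **Pulsed-beam dosimetry.** Dose rate from beam current,
  $\dot D = (I/e)\,L / (A\rho)$ with LET $L$, field area $A$ and density
  $\rho$; chopper timing (pulse-to-pulse distance $2^k/f_\mathrm{base}$),
  duty cycles, mean vs peak dose rate, and irradiation durations for a
  prescribed dose.
* **Irradiated blood volume.** Static blood in the traced vessels,
  $V_\mathrm{static} = \sum_c \frac{\pi d_c^2}{4} \sum_i l_i$ over three
  vessel-thickness classes; flow exchange through entry veins,
  $V_\mathrm{flow} = \sum_j \frac{\pi d_j^2}{4} v t$;
  $V_\mathrm{irr} = V_\mathrm{static} + V_\mathrm{flow}$; irradiated blood
  fraction and mean blood dose
  $D\,V_\mathrm{static}/V_\mathrm{irr}$.
* **Longitudinal inflammation.** Sham-referenced ear swelling
  $ES_i(t) = ET_i(t) - \overline{ET}_\mathrm{sham}(t)$, ordinal
  erythema + desquamation scores (range 0–6), group mean ± SEM curves, peak
  reactions, percent reductions with first-order error propagation, and
  two-sample t-tests.
* **ΔΔCt qPCR.** Housekeeping-normalized, sham-referenced fold changes,
  $FC = 2^{-\Delta\Delta C_t}$, $\log_2 FC = -\Delta\Delta C_t$, with
  per-group summaries.
* **Synthetic data.** Seeded generators for cohorts, vessel traces and Ct
  plates with known ground truth, used throughout the tests for parameter
  recovery.

All user-facing functions take data frames and return tibbles, so stages
chain with the pipe; results have `tidy()`/`glance()` and `autoplot()`
methods.

## Worked example

Reconstruct the irradiation plan of the three dose-rate modes for 33 Gy:

```r
library(flashear)
irradiation_plan(flash_beams(), dose_Gy = 33)
#>   label    mode       peak_current_nA mean_current_nA peak_dose_rate_Gy_s mean_dose_rate_Gy_s duty_cycle duration_s
#> 1 Flash930 continuous            15            15                   929.              929.         1          0.0355
#> 2 Flash9   pulsed                15             0.15                929.                9.29       0.01       3.55
#> 3 Conv     pulsed                 0.4           0.001                24.8              0.0619     0.0025    533.
```

The continuous 15 nA beam delivers ~930 Gy/s; chopping it to 128 ns pulses
every 12.8 µs divides the mean rate by 100 (9.3 Gy/s); dropping the in-pulse
current to 0.4 nA with a 51.2 µs period gives the conventional 0.06 Gy/s,
which needs about nine minutes for 33 Gy.

Estimate the irradiated blood volume on a synthetic vessel trace (calibrated
to a 0.20 µl static volume with four 0.09 mm entry veins) at the three
irradiation durations:

```r
trace <- simulate_vessels(seed = 1)
estimate_blood_volume(trace$segments, trace$entry_veins,
                      time_s = c(0.035, 3.55, 550),
                      label = c("Flash930", "Flash9", "Conv"))
#>   label     time_s static_ul  flow_ul irradiated_ul blood_fraction_pct mean_blood_dose_Gy
#> 1 Flash930   0.035     0.200  0.00178         0.202             0.0102             32.7
#> 2 Flash9     3.55      0.200  0.181           0.381             0.0192             17.3
#> 3 Conv     550         0.200 28.0            28.2               1.42                0.234
```

At 930 Gy/s essentially only the standing blood (0.20 µl, 0.010 % of the
~2 ml total blood) is exposed and receives the full 33 Gy; at 0.06 Gy/s the
blood is exchanged many times, so ~140× more blood (1.4 % of the total) is
irradiated but receives a mean dose of only ~0.23 Gy.

Analyse a simulated longitudinal cohort (group sizes 7/7/9/3/7/9 + 7 sham,
true 33 Gy reductions 40 % and 57 %):

```r
cohort <- simulate_cohort(seed = 1)
cmp <- compare_groups(cohort, dose_Gy = 33, reference = "Conv")
tidy(cmp)
#>   dose_Gy reference group    peak_day_ref peak_day_test reduction_percent reduction_sem
#> 1      33 Conv      Flash9             25            26              46.0          8.84
#> 2      33 Conv      Flash930           25            21              49.9          6.13
autoplot(cmp)
```

A single cohort at these group sizes estimates each reduction with a
sampling SD of 6–9 percentage points; both estimates cover their injected
truths within two SEM here.

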