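# titinflow

Quantitative analysis of titin (and other sarcomeric protein) dynamics in
skeletal muscle cells from time-lapse fluorescence microscopy. The package
is aimed at muscle cell biologists who image fluorescently knocked-in
sarcomere components and need three things quantified:

1. **FRAP kinetics** — how fast labelled protein exchanges in and out of
   the sarcomere lattice. Traces are double-normalized,
   `I_norm(t) = [(I_frap − I_base)/(I_whole − I_base)] · (I_whole,pre / I_frap,pre)`,
   and fitted with one- or two-phase exponential association,
   `y(t) = y0 + Mf [f (1 − e^(−K_fast t)) + (1 − f)(1 − e^(−K_slow t))]`,
   reporting the mobile fraction `Mf = (F_end − F_post)/(F_pre − F_post)`,
   the exchange half-life `t½ = ln2/K`, and the fast-phase percentage
   `100 f`, with nested-model selection by extra-sum-of-squares F-test.
2. **Mixing after cell fusion** — two-channel movies of fusing red-/
   green-labelled myocytes are calibrated against negative and bright
   positive reference cells, thresholded at 20% (weak) and 50% (strong),
   and every pixel classified as only red / majority red / mixed /
   majority green / only green (plus background and a both-weak remainder
   so areas partition the frame exactly). Per-frame class areas in µm²
   give the mixed-area time series, its initial growth slope
   (`spread_rate`, µm²/hr and µm²/s), and the gradient width between the
   50% and 20% crossings of the invading channel.
3. **Diffusion-with-decay consistency** — whether an observed protein
   gradient of width `d` is compatible with passive diffusion (`D`) and
   turnover (half-life `τ`): the steady-state decay length is
   `λ = √(Dτ/ln2)`, the half-life required to confine a gradient to `d`
   is `ln2·d²/D`, and the diffusion coefficient required at a given `τ`
   is `ln2·d²/τ`. A 1-D explicit finite-difference solver
   (`simulate_1d`) validates the closed forms against its analytic
   steady state.

Seeded synthetic-data generators (`gen_frap_trace`, `gen_fixed_cell_trace`,
`gen_fusion_movie`) emit every dataset together with its ground truth, so
all estimators are verified by parameter recovery without any external
data. See the vignette `vignettes/titin-dynamics.Rmd` for the models,
assumptions and numerical choices.

## Worked example

```r
library(titinflow)

# --- FRAP: simulate a Z-disk-like trace and fit it -----------------------
sim <- gen_frap_trace(frap_sim_config(seed = 42))   # Mf 0.73, 37% fast
fit <- frap_fit(sim$trace, model = "auto")
print(fit)
#> FRAP two-phase association fit (22 post-bleach points)
#>        y0        Mf frac_fast    K_fast    K_slow
#>    0.1906    0.5879    0.3845    0.3051    0.0086
#>   mobile fraction 0.726, half-life 24.2 min (0.40 hr)
#>   fast phase 38.5%
#>   model selection: two_phase (F-test p = 4.98e-10)
```

The fitted span `Mf` = 0.588 over a bleach depth `y0` = 0.19 gives a
mobile fraction of 0.73 — the generator's truth — and the F-test correctly
prefers the biphasic model with ~38% fast phase (truth 37%).

```r
# --- Is a 50 um titin gradient compatible with passive diffusion? --------
consistency_report(d_obs = 50, D = 0.3, tau = days_to_seconds(3.5), ln2 = 0.693)
#> Diffusion-with-decay consistency report
#>   inputs: d = 50 um, D = 0.3 um^2/s, tau = 302400 s (3.50 d)
#>   decay length lambda(D, tau) = 361.8 um
#>   tau required for d at this D: 5775 s (96.2 min)
#>   D required for d at this tau: 0.0057 um^2/s
#>   verdict: incompatible (within factor 2 of d: no)
```

A 50 µm gradient cannot be explained by D = 0.3 µm²/s and a 3.5-day
half-life: diffusion that fast with decay that slow would spread the label
over ~360 µm. Either the half-life would have to be under 100 min or `D`
two orders of magnitude smaller — evidence for an additional mechanism
restricting spread.

```r
# --- Mixing after fusion on a synthetic movie ----------------------------
mv <- gen_fusion_movie(fusion_sim_config(fiber_length = 100, fiber_width = 10,
                                         pixel_size = 1, n_frames = 9,
                                         fusion_frame = 2, noise_sd = 0,
                                         source_positions = list(red = 10, green = 90),
                                         seed = 42))
ts <- mixing_timeseries(mv$stack, identity_calibration("red"),
                        identity_calibration("green"),
                        pixel_size = mv$pixel_size, frame_times_hr = mv$times_hr,
                        median_filter = FALSE)
round(ts[, c("time_hr", "area_mixed", "cell_area", "mixed_pct")], 1)
#>   time_hr area_mixed cell_area mixed_pct
#> 1     0.0          0      1000         0
#> 2     0.5          0      1000         0
#> 3     1.0         20      1000         2
#> 4     1.5        160      1000        16
#> 5     2.0        380      1000        38
#> 6     2.5       1000      1000       100
#> 7     3.0       1000      1000       100
#> 8     3.5       1000      1000       100
#> 9     4.0       1000      1000       100
spread_rate(ts)$rate_um2_per_hr
#> [1] 632
```

Two 50 × 10 µm cells fuse at t = 0.5 hr; with D = 0.3 µm²/s for both
species the mixed area (both channels above the 50% threshold) grows to
cover the whole 1000 µm² syncytium within ~2 hr of fusion, at an initial
rate of ~630 µm²/hr.

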