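# annulokin

Mitral annular geometry and deformational kinematics from sonomicrometry.

The mitral annulus is not a passive ring: through each heartbeat it contracts,
becomes more elliptic, and deepens its saddle shape, and the vigor of that
deformation tracks the contractile state of the left ventricle. `annulokin`
implements the full analysis chain used in sonomicrometry studies of annular
dynamics:

1. **Reconstruction** — eight piezoelectric crystals sutured around the
   annulus yield either 3D positions or pairwise ultrasound transit-time
   distances; the latter are embedded into coordinates by classical
   multidimensional scaling with frame-to-frame Procrustes alignment.
2. **Geometry per frame** — a closed periodic cubic spline through the
   ordered crystals, the total-least-squares annular plane, and from them the
   mitral annular area (MAA, shoelace area of the projected curve),
   intercommissural width (ICW) and septolateral diameter (SL) from principal
   axes, the annular circularity index (ACI = SL/ICW), and the non-planarity
   angle (NPA) subtended at the axis juncture by the two saddle horns
   (180° = flat).
3. **Kinematics per beat** — beats are segmented at end-diastole detected
   from the LV pressure upstroke (dP/dt threshold refined to the
   pressure-volume-loop corner); each metric's cyclical reduction (Δr), its
   average deformation velocity over descending segments (v̄), time-normalized
   cycle curves, and fractional change are computed and averaged over three
   consecutive beats.
4. **Hemodynamics and contractility** — two-axis ellipsoid LV volumes,
   body-surface-area indexing (Kelley formula), per-beat pressures/volumes,
   and the end-systolic pressure-volume relationship (ESPVR) slope E_es —
   the load-independent contractility index — from a caval-constriction run.
5. **Study level** — a pipeline over subjects and intervention states with
   per-subject error isolation, and ordinary least-squares regression of
   annular kinematics on contractility with 95% confidence intervals.

Because raw animal recordings are not generally available, the package ships
a ground-truthed synthetic generator: a deforming saddle annulus
(`x = a cosθ, y = b sinθ, z = −h cos2θ`) coupled beat-for-beat to a
time-varying-elastance ventricle, with preload (caval constriction) and
afterload (aortic occlusion) protocols, rigid-body drift, and positional
noise. Every analytic result can therefore be checked against a known truth.

## Worked example

A single frame: the canonical saddle annulus with semi-axes a = 16 mm,
b = 11.2 mm and saddle height h = 2 mm. The closed forms are
MAA = πab = 562.97 mm², ACI = b/a = 0.70, and NPA = 2·atan(b/h) = 159.75°.

```r
library(annulokin)

th <- seq(0, 2 * pi, length.out = 9)[1:8]
saddle <- cbind(16 * cos(th), 11.2 * sin(th), -2 * cos(2 * th))
analyze_frame(saddle)
#> # A tibble: 1 × 8
#>   time_s maa_mm2 sl_mm icw_mm   aci npa_deg flag_degenerate flag_selfintersect
#>    <dbl>   <dbl> <dbl>  <dbl> <dbl>   <dbl> <lgl>           <lgl>
#> 1      0    563.  22.4     32   0.7    160. FALSE           FALSE
```

A full recording: simulate a noiseless baseline run (12 beats at 135 bpm,
sampled at 117 Hz), detect beats from the pressure trace, and summarize the
annular kinematics.

```r
sim <- simulate_protocol(
  annulus_sim_config(noise_sd_mm = 0, rot_deg = 0, trans_mm = 0),
  lv_sim_config(), protocol = "baseline", seed = 1
)
windows <- detect_ed_es(sim$pressure, sim$pressure$v_lv_ml)
geom    <- analyze_geometry(sim$crystals)
kin     <- summarize_kinematics(geom, windows)
kin
#> Annular deformational kinematics over 11 beats
#> # A tibble: 3 × 6
#>   metric  delta_r_mean delta_r_se v_bar_mean v_bar_se n_beats_averaged
#>   <chr>          <dbl>      <dbl>      <dbl>    <dbl>            <int>
#> 1 aci            0.120 0.00000459      0.895 0.000710                3
#> 2 maa_mm2       21.1   0.000895     1006.    0.798                   3
#> 3 npa_deg       10.3   0.000415      130.    0.103                   3
```

The generator prescribed a 21.2% cyclical area reduction, an absolute ACI
reduction of 0.12, and a 10.3% NPA reduction — the chain recovers them from
raw coordinates to within a fraction of a percent. Hemodynamics from the same
record:

```r
hemo <- summarize_hemodynamics(sim$pressure, sim$pressure$v_lv_ml,
                               windows, bw_kg = 58)
hemo
#> Hemodynamic summary over 11 beats (BSA 1.053 m2)
#> # A tibble: 14 × 3
#>    variable       mean        se
#>  1 hr_bpm       135.   0
#>  2 edp_mmhg       9.80 0.0000984
#>  3 spmax_mmhg   162.   0.0361
#>  ...
#>  7 edv_ml       120.   0.00105
#>  9 sv_ml         44.0  0.00168
#> 10 ef_pct        36.7  0.00167
```

Contractility from a caval-constriction (ICC) run — preload falls beat by
beat, the end-systolic points slide down one line, and its slope is E_es:

```r
icc <- simulate_protocol(
  annulus_sim_config(noise_sd_mm = 0, rot_deg = 0, trans_mm = 0),
  lv_sim_config(), protocol = "icc", seed = 2
)
w2 <- detect_ed_es(icc$pressure, icc$pressure$v_lv_ml)
h2 <- summarize_hemodynamics(icc$pressure, icc$pressure$v_lv_ml, w2, bw_kg = 58)
fit <- estimate_ees(h2$per_beat)
fit
#> ESPVR: Ees = 2.666 mmHg/mL, V0 = 15.2 mL, r2 = 1.0000 (n = 10 beats)
```

The simulator's true elastance was 2.66 mmHg/mL with V0 = 15 mL. Broom-style
accessors and plot methods are available throughout:

```r
generics::glance(fit)
#> # A tibble: 1 × 4
#>   r.squared  nobs slope v0_ml
#> 1     1.000    10  2.67  15.2
ggplot2::autoplot(fit)   # ESPVR scatter with the fitted line
ggplot2::autoplot(geom)  # MAA / ACI / NPA through the cardiac cycle
```

At the study level, `simulate_study()` draws a population of subjects whose
prescribed annular deformation is linearly linked to contractility,
`run_pipeline()` analyzes every subject and state with per-subject error
isolation, and `regress_kinematics_on_ees()` quantifies the
kinematics-contractility relationship.

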