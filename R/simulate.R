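#' Configuration for the saddle-annulus motion simulator
#'
#' Defaults describe a healthy open-chest porcine annulus at baseline:
#' end-diastolic annular area of about 607 mm2 per m2 BSA for a 58 kg
#' animal, circularity index 0.71, non-planarity angle 169 degrees, heart
#' rate 135 min-1, and within-beat reductions of 21.2 percent (area),
#' 0.12 (ACI, absolute) and 10.3 percent (NPA). Each metric follows a
#' smooth C1 periodic waveform that peaks at end-diastole (beat phase 0)
#' and bottoms at end-systole (`es_frac` of the beat).
#'
#' @param maa_max_mm2 End-diastolic (maximal) annular area, mm2.
#' @param d_maa Fractional within-beat area reduction (0-1).
#' @param aci_max,d_aci End-diastolic circularity index and its absolute
#'   within-beat reduction.
#' @param npa_max_deg,d_npa End-diastolic non-planarity angle (degrees) and
#'   its fractional within-beat reduction.
#' @param hr_bpm Heart rate, beats per minute.
#' @param es_frac Beat phase of end-systole (fraction of the cycle).
#' @param dt_s Sampling interval (s); default the sonomicrometry 8.53 ms.
#' @param n_beats Number of beats to generate.
#' @param n_crystals Number of annular crystals (equidistant in angle).
#' @param theta_jitter_sd Angular jitter SD (radians) of crystal placement,
#'   emulating imperfect equidistant suturing (fixed per crystal).
#' @param noise_sd_mm SD of i.i.d. Gaussian positional noise per coordinate.
#' @param rot_deg,trans_mm Amplitudes of the slow rigid-body drift (rotation
#'   in degrees, translation in mm).
#' @param drift_period_s Period of the rigid drift (s).
#' @return List of class `annulus_sim_config`.
#' @export
annulus_sim_config <- function(maa_max_mm2 = 607 * bsa_kelley(58),
                               d_maa = 0.212,
                               aci_max = 0.71, d_aci = 0.12,
                               npa_max_deg = 169, d_npa = 0.103,
                               hr_bpm = 135, es_frac = 0.3,
                               dt_s = SONO_DT, n_beats = 12L,
                               n_crystals = 8L, theta_jitter_sd = 0,
                               noise_sd_mm = 0.05,
                               rot_deg = 5, trans_mm = 2,
                               drift_period_s = 3) {
  cfg <- as.list(environment())
  stopifnot(maa_max_mm2 > 0, d_maa >= 0, d_maa < 1,
            aci_max > 0, aci_max <= 1, d_aci >= 0, d_aci < aci_max,
            npa_max_deg > 0, npa_max_deg <= 180, d_npa >= 0, d_npa < 1,
            hr_bpm > 0, es_frac > 0, es_frac < 1,
            dt_s > 0, dt_s < 60 / hr_bpm, n_beats >= 1, n_crystals >= 4)
  structure(cfg, class = "annulus_sim_config")
}

#' Configuration for the time-varying-elastance ventricle simulator
#'
#' The ventricle follows `P(t) = E(t) * (V(t) - V0)` with a raised-cosine
#' activation `E(t)` running from `e_min` to `e_max` over the first
#' `act_frac` of each beat. Ejection against a lumped resistive afterload
#' (effective arterial elastance `ea`) fixes the stroke volume through the
#' standard ventriculo-arterial coupling `SV = Emax (EDV - V0) / (Ea + Emax)`;
#' filling restores end-diastolic volume by the end of the beat. The volume
#' waveform bottoms exactly at the activation peak, so end-systolic points
#' lie on the line `ESP = Emax (ESV - V0)`. Defaults: contractility 2.66
#' mmHg/mL, V0 15 mL, EDV 120 mL, and an afterload giving a stroke volume of
#' 44 mL (EF about 37 percent); `e_min` set so baseline EDP is 9.8 mmHg.
#'
#' @param e_max,e_min End-systolic and diastolic elastance (mmHg/mL).
#' @param v0_ml Volume-axis intercept of the ESPVR (mL).
#' @param edv_ml End-diastolic volume (mL).
#' @param ea Effective arterial elastance (afterload resistance parameter,
#'   mmHg/mL).
#' @param hr_bpm Heart rate (min-1).
#' @param act_frac Duration of the activation (systole) as a fraction of the
#'   beat; the activation peak (end-systole) is at `act_frac / 2`.
#' @param dt_s Sampling interval (s).
#' @param n_beats Beats to generate.
#' @param p_noise_sd,v_noise_sd Gaussian noise SD on pressure (mmHg) and
#'   volume (mL).
#' @return List of class `lv_sim_config`.
#' @export
lv_sim_config <- function(e_max = 2.66, e_min = 9.8 / (120 - 15),
                          v0_ml = 15, edv_ml = 120,
                          ea = 2.66 * (120 - 15) / 44 - 2.66,
                          hr_bpm = 135, act_frac = 0.6,
                          dt_s = SONO_DT, n_beats = 12L,
                          p_noise_sd = 0, v_noise_sd = 0) {
  cfg <- as.list(environment())
  stopifnot(e_max > e_min, e_min > 0, edv_ml > v0_ml, ea > 0,
            hr_bpm > 0, act_frac > 0, act_frac < 1, dt_s > 0, n_beats >= 1)
  structure(cfg, class = "lv_sim_config")
}

# C1 periodic unimodal waveform: 0 at phase 0, 1 at phase `es`, back to 0 at 1
beat_waveform <- function(phi, es) {
  ifelse(phi <= es,
         sin(pi * phi / (2 * es))^2,
         sin(pi * (1 - phi) / (2 * (1 - es)))^2)
}

# NPA (deg) of a saddle with horn height h over half-septolateral span b
npa_from_saddle <- function(h, b) 2 * atan2(b, h) * 180 / pi

#' Simulate crystal trajectories on a deforming saddle annulus
#'
#' Eight (by default) crystals sit at equidistant angles on the closed curve
#' `x = a(t) cos(theta), y = b(t) sin(theta), z = -h(t) cos(2 theta)`
#' (horns high on the septolateral axis, commissures low). The semi-axes and
#' saddle height are driven by prescribed periodic area, circularity and NPA
#' waveforms; the analytic ground truth (`MAA = pi a b`, `ACI = b / a`,
#' `NPA = 2 atan(b / h)`) is recorded alongside. Optional slow rigid-body
#' drift and i.i.d. Gaussian positional noise emulate acquisition
#' imperfections.
#'
#' @param config An [annulus_sim_config()].
#' @param area_mult,h_mult Per-beat multipliers of the area waveform and the
#'   saddle height (scalars or vectors of length `n_beats`), used by the
#'   intervention protocols.
#' @param seed Optional RNG seed.
#' @return List of class `ma_sim` with `crystals` (wide tibble `time_s,
#'   c1_x, ...`), `truth` (per-frame tibble `time_s, beat, phase, maa_mm2,
#'   aci, npa_deg, a_mm, b_mm, h_mm`), `events` (per-beat `beat, t_ed,
#'   t_es`), `per_beat` (ground-truth `beat, metric, value_ed, value_es,
#'   delta_r, v_bar`), and `config`.
#' @export
simulate_annulus <- function(config = annulus_sim_config(),
                             area_mult = 1, h_mult = 1, seed = NULL) {
  stopifnot(inherits(config, "annulus_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  T_beat <- 60 / cf$hr_bpm
  n <- floor(cf$n_beats * T_beat / cf$dt_s)
  tt <- (seq_len(n) - 1L) * cf$dt_s
  beat <- pmin(floor(tt / T_beat) + 1L, cf$n_beats)
  phi <- tt / T_beat - (beat - 1L)
  area_mult <- rep_len(area_mult, cf$n_beats)
  h_mult <- rep_len(h_mult, cf$n_beats)

  w <- beat_waveform(phi, cf$es_frac)
  maa <- cf$maa_max_mm2 * (1 - cf$d_maa * w) * area_mult[beat]
  aci <- cf$aci_max - cf$d_aci * w
  npa0 <- cf$npa_max_deg * (1 - cf$d_npa * w)
  a <- sqrt(maa / (pi * aci))
  b <- a * aci
  h <- b / tan(npa0 * pi / 360) * h_mult[beat]  # b * cot(NPA/2), then flattening
  npa <- npa_from_saddle(h, b)

  theta <- (seq_len(cf$n_crystals) - 1L) * 2 * pi / cf$n_crystals
  if (cf$theta_jitter_sd > 0) theta <- theta + rnorm(cf$n_crystals, 0, cf$theta_jitter_sd)

  xyz <- array(0, dim = c(n, cf$n_crystals, 3))
  for (j in seq_len(cf$n_crystals)) {
    xyz[, j, 1] <- a * cos(theta[j])
    xyz[, j, 2] <- b * sin(theta[j])
    xyz[, j, 3] <- -h * cos(2 * theta[j])
  }

  if (cf$rot_deg > 0 || cf$trans_mm > 0) {
    u <- c(1, 1, 1) / sqrt(3)
    ang <- cf$rot_deg * pi / 180 * sin(2 * pi * tt / cf$drift_period_s)
    tr <- cf$trans_mm * cbind(sin(2 * pi * tt / cf$drift_period_s),
                              sin(2 * pi * tt / cf$drift_period_s + 2),
                              sin(2 * pi * tt / cf$drift_period_s + 4))
    for (i in seq_len(n)) {
      R <- rotation_matrix(u, ang[i])
      xyz[i, , ] <- xyz[i, , ] %*% t(R) + matrix(tr[i, ], cf$n_crystals, 3, byrow = TRUE)
    }
  }
  if (cf$noise_sd_mm > 0) {
    xyz <- xyz + rnorm(length(xyz), 0, cf$noise_sd_mm)
  }

  wide <- matrix(aperm(xyz, c(1, 3, 2)), nrow = n)  # c1_x c1_y c1_z c2_x ...
  colnames(wide) <-as.vector(t(outer(seq_len(cf$n_crystals), c("x", "y", "z"),
                                      function(i, s) paste0("c", i, "_", s))))
  crystals <- dplyr::bind_cols(tibble::tibble(time_s = tt), tibble::as_tibble(wide))

  truth <- tibble::tibble(time_s = tt, beat = beat, phase = phi,
                          maa_mm2 = pi * a * b, aci = aci, npa_deg = npa,
                          a_mm = a, b_mm = b, h_mm = h)
  events <- tibble::tibble(beat = seq_len(cf$n_beats),
                           t_ed = (seq_len(cf$n_beats) - 1L) * T_beat,
                           t_es = ((seq_len(cf$n_beats) - 1L) + cf$es_frac) * T_beat)
  per_beat <- annulus_truth_per_beat(cf, area_mult, h_mult, T_beat)

  structure(list(crystals = crystals, truth = truth, events = events,
                 per_beat = per_beat, config = cf),
            class = "ma_sim")
}

# analytic per-beat ground truth: metric values at ED / ES, cyclical
# reduction, and mean |derivative| over the (monotone) descending segment
annulus_truth_per_beat <- function(cf, area_mult, h_mult, T_beat) {
  rows <- lapply(seq_len(cf$n_beats), function(k) {
    eval_metrics <- function(wv) {
      maa <- cf$maa_max_mm2 * (1 - cf$d_maa * wv) * area_mult[k]
      aci <- cf$aci_max - cf$d_aci * wv
      npa0 <- cf$npa_max_deg * (1 - cf$d_npa * wv)
      a <- sqrt(maa / (pi * aci)); b <- a * aci
      h <- b / tan(npa0 * pi / 360) * h_mult[k]
      c(maa_mm2 = maa, aci = aci, npa_deg = npa_from_saddle(h, b))
    }
    ed <- eval_metrics(0); es <- eval_metrics(1)
    dur <- cf$es_frac * T_beat
    tibble::tibble(
      beat = k,
      metric = c("maa_mm2", "aci", "npa_deg"),
      value_ed = unname(ed), value_es = unname(es),
      delta_r = c(100 * (ed[1] - es[1]) / ed[1],
                  ed[2] - es[2],
                  100 * (ed[3] - es[3]) / ed[3]),
      v_bar = unname(ed - es) / dur
    )
  })
  dplyr::bind_rows(rows)
}

# Rodrigues rotation matrix about unit axis u by angle (radians)
rotation_matrix <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Simulate left-ventricular pressure and volume with a time-varying elastance
#'
#' See [lv_sim_config()] for the model. Per-beat end-diastolic volume and
#' afterload can be modulated (vectors over beats) to emulate preload and
#' afterload interventions.
#'
#' @param config An [lv_sim_config()].
#' @param edv_beats,ea_beats Optional per-beat end-diastolic volume (mL) and
#'   arterial elastance (mmHg/mL); default the config constants.
#' @param seed Optional RNG seed.
#' @return List of class `pv_sim` with `trace` (tibble `time_s, p_lv_mmhg,
#'   v_lv_ml`), `per_beat` (ground truth `beat, edv_ml, esv_ml, sv_ml,
#'   edp_mmhg, esp_mmhg, spmax_mmhg`), `events` (`beat, t_ed, t_es,
#'   i_ed, i_es`), and `config`.
#' @export
simulate_pv <- function(config = lv_sim_config(),
                        edv_beats = NULL, ea_beats = NULL, seed = NULL) {
  stopifnot(inherits(config, "lv_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  T_beat <- 60 / cf$hr_bpm
  nb <- cf$n_beats
  edv <- rep_len(if (is.null(edv_beats)) cf$edv_ml else edv_beats, nb)
  ea <- rep_len(if (is.null(ea_beats)) cf$ea else ea_beats, nb)
  sv <- cf$e_max * (edv - cf$v0_ml) / (ea + cf$e_max)
  if (any(sv <= 0)) stop("non-ejecting parameterization: stroke volume <= 0")

  n <- floor(nb * T_beat / cf$dt_s)
  tt <- (seq_len(n) - 1L) * cf$dt_s
  beat <- pmin(floor(tt / T_beat) + 1L, nb)
  phi <- tt / T_beat - (beat - 1L)
  es_frac <- cf$act_frac / 2

  act <- ifelse(phi < cf$act_frac,
                0.5 * (1 - cos(2 * pi * phi / cf$act_frac)), 0)
  E <- cf$e_min + (cf$e_max - cf$e_min) * act
  v <- edv[beat] - sv[beat] * beat_waveform(phi, es_frac)
  p <- E * (v - cf$v0_ml)

  per_beat <- tibble::tibble(
    beat = seq_len(nb), edv_ml = edv, esv_ml = edv - sv, sv_ml = sv,
    edp_mmhg = cf$e_min * (edv - cf$v0_ml),
    esp_mmhg = cf$e_max * (edv - sv - cf$v0_ml),
    spmax_mmhg = vapply(seq_len(nb), function(k) max(p[beat == k]), numeric(1))
  )
  t_ed <- (seq_len(nb) - 1L) * T_beat
  t_es <- t_ed + es_frac * T_beat
  events <- tibble::tibble(
    beat = seq_len(nb), t_ed = t_ed, t_es = t_es,
    i_ed = pmin(n, round(t_ed / cf$dt_s) + 1L),
    i_es = pmin(n, round(t_es / cf$dt_s) + 1L)
  )

  if (cf$p_noise_sd > 0) p <- p + rnorm(n, 0, cf$p_noise_sd)
  if (cf$v_noise_sd > 0) v <- v + rnorm(n, 0, cf$v_noise_sd)

  structure(list(trace = tibble::tibble(time_s = tt, p_lv_mmhg = p, v_lv_ml = v),
                 per_beat = per_beat, events = events, config = cf),
            class = "pv_sim")
}

#' Simulate a full acquisition under a loading-intervention protocol
#'
#' Couples the saddle-annulus and elastance simulators under a shared beat
#' clock. `"baseline"` applies no modulation. `"icc"` (inferior caval
#' constriction) reduces end-diastolic volume geometrically beat by beat at
#' fixed contractility -- the simulated ESPVR is exactly linear -- and scales
#' the annular area down with the ventricle (`EDV^(2/3)` coupling).
#' `"ao"` (aortic occlusion) steps the arterial elastance up towards a
#' plateau of peak systolic pressure while dilating the annulus and
#' flattening its saddle.
#'
#' @param annulus_cfg An [annulus_sim_config()].
#' @param lv_cfg An [lv_sim_config()]; its heart rate, sampling interval and
#'   beat count override the annulus config so the two stay synchronous.
#' @param protocol `"baseline"`, `"icc"`, or `"ao"`.
#' @param seed Optional RNG seed.
#' @param icc_decay Per-beat EDV decay factor during ICC.
#' @param ao_factor,ao_rate Target multiplier of the arterial elastance and
#'   geometric approach rate during AO.
#' @param ao_area_gain,ao_h_loss Fractional annular dilation and saddle
#'   flattening at full occlusion.
#' @return List of class `ma_sim_dataset`: `crystals`, `pressure` (tibble
#'   `time_s, p_lv_mmhg, v_lv_ml`), `geometry_truth`, `events`,
#'   `per_beat_geometry`, `per_beat_hemo`, `protocol`, `configs`.
#' @export
simulate_protocol <- function(annulus_cfg = annulus_sim_config(),
                              lv_cfg = lv_sim_config(),
                              protocol = c("baseline", "icc", "ao"),
                              seed = NULL,
                              icc_decay = 0.95,
                              ao_factor = 2.2, ao_rate = 0.7,
                              ao_area_gain = 0.10, ao_h_loss = 0.30) {
  protocol <- match.arg(protocol)
  if (!is.null(seed)) set.seed(seed)
  # shared beat clock
  annulus_cfg$hr_bpm <- lv_cfg$hr_bpm
  annulus_cfg$dt_s <- lv_cfg$dt_s
  annulus_cfg$n_beats <- lv_cfg$n_beats
  annulus_cfg$es_frac <- lv_cfg$act_frac / 2
  nb <- lv_cfg$n_beats
  k <- seq_len(nb) - 1L

  if (protocol == "baseline") {
    edv <- NULL; ea <- NULL; area_mult <- 1; h_mult <- 1
  } else if (protocol == "icc") {
    edv <- lv_cfg$edv_ml * icc_decay^k
    ea <- NULL
    area_mult <- (edv / lv_cfg$edv_ml)^(2 / 3)
    h_mult <- 1
  } else {
    ramp <- 1 - ao_rate^k
    ea <- lv_cfg$ea * (1 + (ao_factor - 1) * ramp)
    edv <- NULL
    area_mult <- 1 + ao_area_gain * ramp
    h_mult <- 1 - ao_h_loss * ramp
  }

  pv <- simulate_pv(lv_cfg, edv_beats = edv, ea_beats = ea)
  ann <- simulate_annulus(annulus_cfg, area_mult = area_mult, h_mult = h_mult)

  structure(list(crystals = ann$crystals,
                 pressure = pv$trace,
                 geometry_truth = ann$truth,
                 events = pv$events,
                 per_beat_geometry = ann$per_beat,
                 per_beat_hemo = pv$per_beat,
                 protocol = protocol,
                 configs = list(annulus = ann$config, lv = pv$config)),
            class = "ma_sim_dataset")
}

#' Write a simulated dataset to disk in the analysis CSV dialects
#'
#' Writes `crystals.csv` (wide crystal coordinates), `pressure.csv`
#' (`time_s, p_lv_mmhg, v_lv_ml`), and `truth.json` (per-frame and per-beat
#' ground truth, events, protocol, config echo).
#'
#' @param sim A `ma_sim_dataset` from [simulate_protocol()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ma_sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$crystals, file.path(dir, "crystals.csv"))
  readr::write_csv(sim$pressure, file.path(dir, "pressure.csv"))
  truth <- list(protocol = sim$protocol,
                geometry = sim$geometry_truth,
                events = sim$events,
                per_beat_geometry = sim$per_beat_geometry,
                per_beat_hemo = sim$per_beat_hemo,
                configs = lapply(sim$configs, unclass))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
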