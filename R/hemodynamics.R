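#' Porcine body surface area (Kelley formula)
#'
#' `BSA = 734 * BW^0.656`, evaluated in cm2 and converted to m2. Used to
#' index volumes and annular areas across animals of different weight.
#'
#' @param bw_kg Body weight (kg), positive.
#' @return BSA in m2.
#' @examples
#' bsa_kelley(58) # ~1.053 m2
#' @export
bsa_kelley <- function(bw_kg) {
  if (any(!is.finite(bw_kg)) || any(bw_kg <= 0)) stop("body weight must be positive")
  734 * bw_kg^0.656 / 1e4
}

#' Two-axis ellipsoid left-ventricular volume
#'
#' `V = pi/6 * D^2 * L`, with `D` the equatorial anteroposterior short-axis
#' diameter and `L` the apicobasal long axis, converted from mm3 to mL.
#'
#' @param d_mm Short-axis diameter (mm).
#' @param l_mm Long-axis length (mm).
#' @return Volume in mL (vectorized).
#' @examples
#' lv_volume_ellipsoid(60, 80) # 150.8 mL
#' @export
lv_volume_ellipsoid <- function(d_mm, l_mm) {
  if (any(d_mm < 0) || any(l_mm < 0)) stop("dimensions must be non-negative")
  pi / 6 * d_mm^2 * l_mm / 1000
}

#' Correct epicardial dimensions for wall thickness
#'
#' The sonomicrometry crystals sit on the epicardium; the cavity short axis
#' loses twice the equatorial wall thickness and the long axis the apical
#' thickness. Within a beat the equatorial thickness is linearly interpolated
#' between its end-diastolic and end-systolic values via `phase` (0 = ED,
#' 1 = ES).
#'
#' @param d_epi_mm,l_epi_mm Epicardial short/long axes (mm).
#' @param wt_ed_mm,wt_es_mm Equatorial wall thickness at ED and ES (mm).
#' @param wt_apical_mm Apical wall thickness (mm).
#' @param phase Contraction phase in `[0, 1]` (vectorized).
#' @return List with `d_endo_mm`, `l_endo_mm`, `wt_mm` (interpolated
#'   equatorial thickness).
#' @export
correct_for_wall_thickness <- function(d_epi_mm, l_epi_mm,
                                       wt_ed_mm, wt_es_mm, wt_apical_mm,
                                       phase = 0) {
  wt <- wt_ed_mm + (wt_es_mm - wt_ed_mm) * phase
  d <- d_epi_mm - 2 * wt
  l <- l_epi_mm - wt_apical_mm
  if (any(d <= 0) || any(l <= 0)) {
    stop("wall-thickness correction leaves a non-positive cavity dimension")
  }
  list(d_endo_mm = d, l_endo_mm = l, wt_mm = wt)
}

#' Detect end-diastole, end-systole, and peak systole per beat
#'
#' End-diastole is the onset of the rapid rise of LV pressure: the sample
#' where the smoothed dP/dt crosses a threshold (a fraction of the
#' within-beat dP/dt maximum, default 10 percent), refined to the coincident
#' local maximum of the volume trace (the lower-right corner of the PV loop).
#' End-systole is the minimum LV volume within each ED-to-ED window (the
#' upper-left corner); peak systole the pressure maximum. A disagreement of
#' more than `corner_tol` samples between the dP/dt crossing and the volume
#' corner sets a per-beat warning flag.
#'
#' @param pressure Data frame with columns `time_s` and `p_lv_mmhg`.
#' @param volume LV volume series (mL), same length and time base.
#' @param threshold_frac ED threshold as a fraction of within-beat dP/dt max.
#' @param smooth_n Moving-average window (samples) applied to the pressure
#'   and to its derivative before thresholding.
#' @param corner_tol Samples of ED / volume-corner disagreement tolerated
#'   before flagging.
#' @return Tibble of complete beat windows: `beat, i_ed, i_es, i_spmax,
#'   t_start, t_end, t_es, t_spmax, flag_corner` (indices into the input
#'   series).
#' @export
detect_ed_es <- function(pressure, volume, threshold_frac = 0.10,
                         smooth_n = 5L, corner_tol = 5L) {
  tt <- pressure$time_s
  p <- pressure$p_lv_mmhg
  stopifnot(length(p) == length(volume))
  n <- length(p)
  if (n < 20L) stop("pressure record too short")
  dt <- stats::median(diff(tt))

  ps <- moving_average(p, smooth_n)
  dpdt <- c(NA, (ps[3:n] - ps[1:(n - 2)]) / (2 * dt), NA)
  dpdt <- moving_average(ifelse(is.na(dpdt), 0, dpdt), smooth_n)

  dmax <- max(dpdt, na.rm = TRUE)
  if (!is.finite(dmax) || dmax <= 0 ||
      dmax - min(dpdt, na.rm = TRUE) < 1e-6 * max(abs(p), 1)) {
    stop("no dP/dt upstrokes found (pressure trace flat?)")
  }

  # pass 1: candidate EDs from a global threshold, with a refractory merge
  thr <- threshold_frac * dmax
  up <- which(dpdt[-n] < thr & dpdt[-1] >= thr)
  if (!length(up)) stop("no dP/dt threshold crossings found")
  if (length(up) > 1L) {
    gap <- stats::median(diff(up))
    up <- up[c(TRUE, diff(up) > 0.5 * gap)]
  }
  if (length(up) < 2L) stop("fewer than one complete beat in the record")

  # pass 2: per-beat re-threshold and refinement to the volume corner
  beat_len <- stats::median(diff(up))
  windows <- vector("list", length(up) - 1L)
  for (k in seq_len(length(up) - 1L)) {
    refine_ed <- function(cross) {
      hw <- as.integer(round(0.15 * beat_len))
      lo <- max(1L, cross - hw)
      hi <- min(n, cross + hw)
      vol_corner <- lo - 1L + which.max(volume[lo:hi])
      list(i = vol_corner, flag = abs(cross - vol_corner) > corner_tol)
    }
    # within-beat threshold around the candidate upstroke
    wlo <- max(1L, up[k] - as.integer(round(0.2 * beat_len)))
    whi <- min(n, up[k] + as.integer(round(0.8 * beat_len)))
    thr_b <- threshold_frac * max(dpdt[wlo:whi], na.rm = TRUE)
    seg <- wlo:(whi - 1L)
    cr <- seg[dpdt[seg] < thr_b & dpdt[seg + 1L] >= thr_b]
    cross <- if (length(cr)) cr[which.min(abs(cr - up[k]))] else up[k]
    ed <- refine_ed(cross)

    # window end: the next beat's refined ED
    wlo2 <- max(1L, up[k + 1L] - as.integer(round(0.2 * beat_len)))
    whi2 <- min(n, up[k + 1L] + as.integer(round(0.8 * beat_len)))
    thr_b2 <- threshold_frac * max(dpdt[wlo2:whi2], na.rm = TRUE)
    seg2 <- wlo2:(whi2 - 1L)
    cr2 <- seg2[dpdt[seg2] < thr_b2 & dpdt[seg2 + 1L] >= thr_b2]
    cross2 <- if (length(cr2)) cr2[which.min(abs(cr2 - up[k + 1L]))] else up[k + 1L]
    ed2 <- refine_ed(cross2)

    span <- ed$i:(ed2$i - 1L)
    i_es <- span[which.min(volume[span])]
    i_sp <- span[which.max(p[span])]
    windows[[k]] <- tibble::tibble(
      beat = k, i_ed = ed$i, i_es = i_es, i_spmax = i_sp,
      t_start = tt[ed$i], t_end = tt[ed2$i], t_es = tt[i_es],
      t_spmax = tt[i_sp], flag_corner = ed$flag
    )
  }
  dplyr::bind_rows(windows)
}

#' Per-beat and summary hemodynamics
#'
#' Extracts per-beat pressures, volumes and derived indices from a
#' pressure/volume record and its beat windows, indexes volumes to body
#' surface area (Kelley formula), and averages the first `n_aggregate`
#' consecutive beats. Identities per beat: `SV = EDV - ESV`,
#' `EF = 100 * SV / EDV`, `CI = HR * SV / (1000 * BSA)`.
#'
#' @param pressure Data frame `time_s, p_lv_mmhg`.
#' @param volume Volume series (mL).
#' @param windows Beat windows from [detect_ed_es()].
#' @param bw_kg Body weight (kg) for BSA indexing.
#' @param n_aggregate Beats averaged in the summary (default 3).
#' @param smooth_n Smoothing window for the reported dP/dt extrema.
#' @return List of class `hemodynamics`: `per_beat` tibble (`beat, hr_bpm,
#'   edp_mmhg, spmax_mmhg, esp_mmhg, dpdt_max, dpdt_min, edv_ml, esv_ml,
#'   sv_ml, ef_pct, edv_i, esv_i, sv_i, ci, flag_nonejecting`), `summary`
#'   (means +/- SE over the aggregated beats), and `bsa_m2`.
#' @export
summarize_hemodynamics <- function(pressure, volume, windows, bw_kg,
                                   n_aggregate = 3L, smooth_n = 5L) {
  tt <- pressure$time_s
  p <- pressure$p_lv_mmhg
  n <- length(p)
  dt <- stats::median(diff(tt))
  bsa <- bsa_kelley(bw_kg)
  ps <- moving_average(p, smooth_n)
  dpdt <- c(NA, (ps[3:n] - ps[1:(n - 2)]) / (2 * dt), NA)

  rows <- lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k, ]
    span <- w$i_ed:(max(w$i_ed + 1L, which(tt < w$t_end) |> max()))
    edv <- volume[w$i_ed]; esv <- volume[w$i_es]
    sv <- edv - esv
    dur <- w$t_end - w$t_start
    hr <- 60 / dur
    tibble::tibble(
      beat = w$beat, hr_bpm = hr,
      edp_mmhg = p[w$i_ed], spmax_mmhg = p[w$i_spmax], esp_mmhg = p[w$i_es],
      dpdt_max = max(dpdt[span], na.rm = TRUE),
      dpdt_min = min(dpdt[span], na.rm = TRUE),
      edv_ml = edv, esv_ml = esv, sv_ml = sv,
      ef_pct = 100 * sv / edv,
      edv_i = edv / bsa, esv_i = esv / bsa, sv_i = sv / bsa,
      ci = hr * sv / (1000 * bsa),
      flag_nonejecting = sv <= 0
    )
  })
  per_beat <- dplyr::bind_rows(rows)
  if (any(per_beat$flag_nonejecting)) {
    warning(sum(per_beat$flag_nonejecting), " non-ejecting beat(s) flagged")
  }

  num <- setdiff(names(per_beat), c("beat", "flag_nonejecting"))
  agg <- lapply(num, function(v) aggregate_beats(per_beat[[v]], n_aggregate))
  summary <- tibble::tibble(
    variable = num,
    mean = vapply(agg, `[[`, numeric(1), "mean"),
    se = vapply(agg, `[[`, numeric(1), "se")
  )
  structure(list(per_beat = per_beat, summary = summary, bsa_m2 = bsa),
            class = "hemodynamics")
}

#' @export
print.hemodynamics <- function(x, ...) {
  cat("Hemodynamic summary over", nrow(x$per_beat), "beats (BSA",
      round(x$bsa_m2, 3), "m2)\n")
  print(x$summary)
  invisible(x)
}

#' Locate the measurement beat for an intervention state
#'
#' During inferior caval constriction the measurement point is the first
#' beat whose end-diastolic pressure has fallen to 80 percent of the
#' reference (a 20 percent drop); after aortic occlusion it is the first
#' beat at which peak systolic pressure has plateaued (consecutive-beat
#' change below `plateau_frac`).
#'
#' @param per_beat Per-beat tibble from [summarize_hemodynamics()].
#' @param state `"icc"` or `"ao"`.
#' @param baseline_edp Reference EDP (mmHg), required for `"icc"`.
#' @param plateau_frac Relative SPmax change defining the plateau
#'   (default 0.02).
#' @return The beat id of the selected measurement beat.
#' @export
select_state_beat <- function(per_beat, state = c("icc", "ao"),
                              baseline_edp = NULL, plateau_frac = 0.02) {
  state <- match.arg(state)
  if (state == "icc") {
    if (is.null(baseline_edp)) stop("`baseline_edp` required for ICC")
    hit <- which(per_beat$edp_mmhg <= 0.8 * baseline_edp)
    if (!length(hit)) stop("no beat reaches a 20% drop in end-diastolic pressure")
    per_beat$beat[hit[1]]
  } else {
    sp <- per_beat$spmax_mmhg
    if (length(sp) < 2L) stop("need at least 2 beats to find an SPmax plateau")
    rel <- abs(diff(sp)) / abs(sp[-length(sp)])
    hit <- which(rel < plateau_frac)
    if (!length(hit)) stop("peak systolic pressure never plateaus")
    per_beat$beat[hit[1] + 1L]
  }
}

#' Contractility from the end-systolic pressure-volume relationship
#'
#' Ordinary least-squares fit of end-systolic pressure on end-systolic
#' volume over up to `max_beats` sequential beats of a caval-constriction
#' run. The slope is the end-systolic elastance (load-independent
#' contractility index); the x-intercept is the volume-axis intercept V0.
#'
#' @param per_beat Tibble with columns `esv_ml` and `esp_mmhg` (one row per
#'   beat), e.g. from [summarize_hemodynamics()].
#' @param max_beats Maximum number of beats used (default 10, taken from the
#'   start of the run).
#' @return Object of class `ees_fit`: list with `slope` (mmHg/mL), `v0_ml`,
#'   `r_squared`, `n_beats`, `data`, and the underlying `lm` fit.
#' @export
estimate_ees <- function(per_beat, max_beats = 10L) {
  d <- dplyr::as_tibble(per_beat)[, c("esv_ml", "esp_mmhg")]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d <- utils::head(d, max_beats)
  if (nrow(d) < 3L) stop("need at least 3 beats with end-systolic points")
  if (stats::var(d$esv_ml) < 1e-12) stop("end-systolic volumes do not vary")
  fit <- stats::lm(esp_mmhg ~ esv_ml, data = d)
  slope <- unname(coef(fit)[2])
  structure(
    list(slope = slope,
         v0_ml = -unname(coef(fit)[1]) / slope,
         r_squared = summary(fit)$r.squared,
         n_beats = nrow(d),
         data = d, fit = fit),
    class = "ees_fit"
  )
}

#' @export
print.ees_fit <- function(x, ...) {
  cat(sprintf("ESPVR: Ees = %.3f mmHg/mL, V0 = %.1f mL, r2 = %.4f (n = %d beats)\n",
              x$slope, x$v0_ml, x$r_squared, x$n_beats))
  invisible(x)
}

#' @export
tidy.ees_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("v0_ml", "ees_mmhg_ml"),
    estimate = c(x$v0_ml, x$slope),
    std.error = c(NA_real_, s[2, 2]),
    statistic = c(NA_real_, s[2, 3]),
    p.value = c(NA_real_, s[2, 4])
  )
}

#' @export
glance.ees_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n_beats,
                 slope = x$slope, v0_ml = x$v0_ml)
}

#' @export
autoplot.ees_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$esv_ml, y = .data$esp_mmhg)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "end-systolic volume (mL)",
                  y = "end-systolic pressure (mmHg)",
                  title = sprintf("ESPVR: Ees = %.2f mmHg/mL", object$slope))
}

#' Read an LV pressure CSV (`time_s, p_lv_mmhg[, p_la_mmhg, p_ao_mmhg]`)
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_pressure_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "p_lv_mmhg") %in% names(x))) {
    stop("expected columns `time_s` and `p_lv_mmhg`")
  }
  x
}
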