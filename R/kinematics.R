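#' Slice a geometry time series into heartbeats
#'
#' Assigns every geometry frame to the beat window (end-diastole to next
#' end-diastole) that contains it. Windows normally come from
#' [detect_ed_es()] on the simultaneous pressure/volume record. Beats that
#' cover fewer than `min_samples` geometry frames are discarded with a
#' warning. Adjacent windows partition the record: each frame belongs to at
#' most one beat (`t_start <= time_s < t_end`).
#'
#' @param geometry Data frame with `time_s` plus metric columns (e.g. the
#'   output of [analyze_geometry()]).
#' @param windows Beat-window tibble with columns `beat, t_start, t_end` (and
#'   optionally `t_es`, `t_spmax`), e.g. from [detect_ed_es()].
#' @param min_samples Minimum frames per beat (default 10).
#' @return The geometry tibble with a `beat` column, restricted to frames
#'   inside complete windows.
#' @export
segment_beats <- function(geometry, windows, min_samples = 10L) {
  geometry <- dplyr::as_tibble(geometry)
  if (!nrow(windows)) stop("empty beat-window list")
  if (max(windows$t_end) <= min(geometry$time_s) ||
      min(windows$t_start) >= max(geometry$time_s)) {
    stop("beat windows do not overlap the geometry time range")
  }
  idx <- findInterval(geometry$time_s, windows$t_start)
  beat <- ifelse(idx >= 1 & geometry$time_s < windows$t_end[pmax(idx, 1L)],
                 windows$beat[pmax(idx, 1L)], NA_integer_)
  out <- dplyr::mutate(geometry, beat = beat)
  out <- dplyr::filter(out, !is.na(.data$beat))
  counts <- table(out$beat)
  short <- as.integer(names(counts)[counts < min_samples])
  if (length(short)) {
    warning("discarding ", length(short), " beat(s) with fewer than ",
            min_samples, " samples")
    out <- dplyr::filter(out, !.data$beat %in% short)
  }
  out
}

#' Maximal cyclical reduction of a metric within one beat
#'
#' Percent mode (used for annular area and non-planarity angle):
#' `100 * (max - min) / max`; absolute mode (used for the circularity
#' index): `max - min`.
#'
#' @param x Metric values over one beat.
#' @param mode `"percent"` or `"absolute"`.
#' @return Non-negative scalar.
#' @examples
#' cyclical_reduction(c(650, 600, 550, 620))          # 15.38 %
#' cyclical_reduction(c(0.72, 0.60), mode = "absolute") # 0.12
#' @export
cyclical_reduction <- function(x, mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]
  if (!length(x)) stop("all values missing")
  if (length(x) < 2L) stop("need at least 2 samples")
  if (mode == "percent") 100 * (max(x) - min(x)) / max(x) else max(x) - min(x)
}

#' Average velocity of geometric deformation
#'
#' Mean magnitude of the time derivative over the descending segments of the
#' cyclical curve. Descending runs are located on the central-difference
#' derivative of a `smooth_n`-sample moving-average of the signal (a run is
#' at least `min_run` consecutive samples with negative derivative), then
#' each run is anchored to the enclosing local extrema of the raw signal
#' with parabolic sub-sample refinement. The mean first derivative over a
#' segment is its net drop over its duration, so the estimate is
#' `sum(drops) / sum(durations)` across runs, a positive magnitude in metric
#' units per second.
#'
#' @param x Metric values over one beat.
#' @param time Sample times (s), uniformly spaced.
#' @param smooth_n Moving-average window used for run detection (samples,
#'   odd; default 5).
#' @param min_run Minimum descending-run length (default 3).
#' @return Positive scalar, or `NA` with a warning when the beat contains no
#'   descending segment.
#' @export
deformation_velocity <- function(x, time, smooth_n = 5L, min_run = 3L) {
  stopifnot(length(x) == length(time))
  n <- length(x)
  if (n < min_run + 2L) stop("too few samples for a descending run")
  xs <- moving_average(x, smooth_n)
  d <- c(NA, (xs[3:n] - xs[1:(n - 2)]) / (time[3:n] - time[1:(n - 2)]), NA)
  neg <- !is.na(d) & d < 0
  runs <- rle(neg)
  keep <- runs$values & runs$lengths >= min_run
  if (!any(keep)) {
    warning("no descending segment in beat: deformation velocity undefined")
    return(NA_real_)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  refine <- function(i) refine_vertex(x, time, i)

  drop_sum <- 0; dur_sum <- 0
  for (r in which(keep)) {
    i1 <- starts[r]; i2 <- ends[r]
    while (i1 > 1L && x[i1 - 1L] >= x[i1]) i1 <- i1 - 1L   # back to local max
    while (i2 < n && x[i2 + 1L] <= x[i2]) i2 <- i2 + 1L    # on to local min
    p1 <- refine(i1); p2 <- refine(i2)
    if (p2["t"] > p1["t"] && p1["x"] > p2["x"]) {
      drop_sum <- drop_sum + (p1["x"] - p2["x"])
      dur_sum <- dur_sum + (p2["t"] - p1["t"])
    }
  }
  if (dur_sum <= 0) {
    warning("no descending segment in beat: deformation velocity undefined")
    return(NA_real_)
  }
  unname(drop_sum / dur_sum)
}

# Sub-sample extremum refinement around sample i: fits a "kinked parabola"
# (two one-sided quadratic branches sharing the vertex) to up to 7 local
# samples, scanning the vertex time over +/- 0.6 samples. Physiological
# cycle curves often change curvature abruptly at their extrema, where a
# single parabola mislocates the vertex by a sizeable fraction of a sample.
refine_vertex <- function(x, time, i, halfwidth = 3L) {
  n <- length(x)
  lo <- max(1L, i - halfwidth); hi <- min(n, i + halfwidth)
  idx <- lo:hi
  if (length(idx) < 3L) return(c(t = time[i], x = x[i]))
  tl <- time[idx]; xl <- x[idx]
  dt <- stats::median(diff(time))

  ls_fit <- function(A) {
    cf <- tryCatch(qr.coef(qr(A), xl), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(list(rss = Inf, x = NA_real_))
    r <- xl - A %*% cf
    list(rss = sum(r^2), x = cf[1])
  }
  fit_at <- function(ts) {
    u <- tl - ts
    left <- u < 0
    quad <- if (any(left) && any(!left)) {
      ls_fit(cbind(1, ifelse(left, u^2, 0), ifelse(!left, u^2, 0)))
    } else {
      ls_fit(cbind(1, u^2))
    }
    # "V" model: two straight branches meeting at the vertex (kinks)
    vee <- if (any(left) && any(!left)) {
      ls_fit(cbind(1, ifelse(left, u, 0), ifelse(!left, u, 0)))
    } else {
      list(rss = Inf, x = NA_real_)
    }
    if (vee$rss < quad$rss) vee else quad
  }
  opt <- stats::optimize(function(ts) fit_at(ts)$rss,
                         c(time[i] - 0.6 * dt, time[i] + 0.6 * dt))
  best <- fit_at(opt$minimum)
  # a plain line explains the samples equally well: no resolvable extremum,
  # keep the sample itself (e.g. run truncated at a record boundary)
  line <- ls_fit(cbind(1, tl))
  if (!is.finite(best$rss) || line$rss <= best$rss + 1e-12 * sum(xl^2)) {
    return(c(t = time[i], x = x[i]))
  }
  c(t = opt$minimum, x = unname(best$x))
}

# centred moving average, window shrinking symmetrically at the edges
moving_average <- function(x, n = 5L) {
  if (n <= 1L) return(x)
  half <- n %/% 2L
  len <- length(x)
  vapply(seq_len(len), function(i) {
    h <- min(half, i - 1L, len - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Resample one beat onto normalized time
#'
#' Linear temporal interpolation onto `K` equispaced points of normalized
#' time in `[0, 1]`, so beats of different durations and heart rates can be
#' averaged pointwise. Endpoints are preserved exactly.
#'
#' @param x Metric values over one beat.
#' @param time Sample times (s).
#' @param K Number of output points (>= 2, default 100).
#' @return Tibble `t_norm, value` with `K` rows.
#' @export
normalize_beat <- function(x, time, K = 100L) {
  if (K < 2L) stop("`K` must be at least 2")
  stopifnot(length(x) == length(time), length(x) >= 2L)
  tn <- (time - time[1]) / (time[length(time)] - time[1])
  out <- stats::approx(tn, x, xout = seq(0, 1, length.out = K))
  tibble::tibble(t_norm = out$x, value = out$y)
}

#' Fractional change relative to the previous beat's end-systolic value
#'
#' `100 * (x - x_es_prev) / x_es_prev` per sample. The first beat of a
#' record has no predecessor and gets `NA`.
#'
#' @param x Metric values over one beat.
#' @param previous_es End-systolic value of the same metric in the previous
#'   beat (must be positive).
#' @return Percent curve, same length as `x`.
#' @examples
#' fractional_change(607, 525) # +15.62 %
#' @export
fractional_change <- function(x, previous_es) {
  if (is.na(previous_es)) return(rep(NA_real_, length(x)))
  if (previous_es <= 0) stop("`previous_es` must be positive")
  100 * (x - previous_es) / previous_es
}

#' Average consecutive beats
#'
#' Mean and standard error over `n` consecutive beats, per scalar metric and
#' pointwise across normalized curves.
#'
#' @param x Numeric vector (one value per beat) or a matrix with one row per
#'   beat (e.g. normalized curves).
#' @param n Number of consecutive beats to average (default 3); the first
#'   `n` are used.
#' @return List with `mean` and `se` (scalars or vectors).
#' @examples
#' aggregate_beats(c(20, 21, 22)) # mean 21, se 0.577
#' @export
aggregate_beats <- function(x, n = 3L) {
  if (is.matrix(x)) {
    if (nrow(x) < n) stop("need at least ", n, " consecutive valid beats")
    x <- x[seq_len(n), , drop = FALSE]
    list(mean = colMeans(x), se = apply(x, 2, stats::sd) / sqrt(n))
  } else {
    x <- x[!is.na(x)]
    if (length(x) < n) stop("need at least ", n, " consecutive valid beats")
    x <- x[seq_len(n)]
    list(mean = mean(x), se = stats::sd(x) / sqrt(n))
  }
}

#' Per-beat deformational kinematics for one or more metrics
#'
#' For every complete beat and every requested metric column, computes the
#' maximal cyclical reduction (percent for area and NPA, absolute for ACI),
#' the average deformation velocity over descending segments, the
#' `K`-point time-normalized cycle curve, and the fractional change relative
#' to the previous beat's end-systolic configuration.
#'
#' @param geometry Geometry time series (`time_s` + metric columns).
#' @param windows Beat windows from [detect_ed_es()] (columns `beat,
#'   t_start, t_end, t_es`).
#' @param metrics Named character vector: names are metric columns in
#'   `geometry`, values the reduction mode (`"percent"` or `"absolute"`).
#' @param K Points per normalized curve.
#' @param n_aggregate Beats entering the summary average (default 3).
#' @return List of class `annulus_kinematics` with tibbles `per_beat`
#'   (`metric, beat, delta_r, v_bar`), `curves` (`metric, beat, t_norm,
#'   value, frac_change`), and `summary` (`metric, delta_r_mean, delta_r_se,
#'   v_bar_mean, v_bar_se, n_beats_averaged`).
#' @export
summarize_kinematics <- function(geometry,
                                 windows,
                                 metrics = c(maa_mm2 = "percent",
                                             aci = "absolute",
                                             npa_deg = "percent"),
                                 K = 100L,
                                 n_aggregate = 3L) {
  seg <- segment_beats(geometry, windows)
  beats <- sort(unique(seg$beat))
  per_beat <- list(); curves <- list()

  for (m in names(metrics)) {
    if (!m %in% names(seg)) stop("metric column not found: ", m)
    prev_es <- NA_real_
    for (b in beats) {
      sub <- seg[seg$beat == b, ]
      x <- sub[[m]]; tt <- sub$time_s
      dr <- cyclical_reduction(x, mode = metrics[[m]])
      vb <- suppressWarnings(deformation_velocity(x, tt))
      nb <- normalize_beat(x, tt, K = K)
      nb$frac_change <- fractional_change(nb$value, prev_es)
      per_beat[[length(per_beat) + 1L]] <-
        tibble::tibble(metric = m, beat = b, delta_r = dr, v_bar = vb)
      curves[[length(curves) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(metric = m, beat = b), nb)
      # end-systolic value of this beat, for the next beat's fractional change
      w <- windows[windows$beat == b, ]
      prev_es <- if (nrow(w) && "t_es" %in% names(w) && !is.na(w$t_es[1])) {
        x[which.min(abs(tt - w$t_es[1]))]
      } else {
        min(x)
      }
    }
  }
  per_beat <- dplyr::bind_rows(per_beat)
  curves <- dplyr::bind_rows(curves)
  summary <- dplyr::group_by(per_beat, .data$metric)
  summary <- dplyr::summarise(
    summary,
    delta_r_mean = aggregate_beats(.data$delta_r, n_aggregate)$mean,
    delta_r_se = aggregate_beats(.data$delta_r, n_aggregate)$se,
    v_bar_mean = aggregate_beats(.data$v_bar, n_aggregate)$mean,
    v_bar_se = aggregate_beats(.data$v_bar, n_aggregate)$se,
    n_beats_averaged = n_aggregate,
    .groups = "drop"
  )
  structure(list(per_beat = per_beat, curves = curves, summary = summary),
            class = "annulus_kinematics")
}

#' @export
print.annulus_kinematics <- function(x, ...) {
  cat("Annular deformational kinematics over",
      length(unique(x$per_beat$beat)), "beats\n")
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.annulus_kinematics <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$t_norm, y = .data$value,
                               group = .data$beat)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "normalized time", y = NULL,
                  title = "Time-normalized cyclical deformation")
}
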