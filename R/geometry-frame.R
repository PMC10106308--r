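#' Full geometric analysis of one annular frame
#'
#' Runs the whole per-frame chain: closed periodic spline through the ordered
#' crystal positions, least-squares plane fit and projection, shoelace area
#' (MAA), principal axes, axis/annulus intersections, intercommissural width
#' (ICW), septolateral diameter (SL), circularity index (ACI = SL/ICW) and
#' non-planarity angle (NPA) at the axis juncture.
#'
#' @param points 8 x 3 numeric matrix of crystal positions (mm), ordered
#'   circularly around the annulus.
#' @param time Acquisition time of the frame (s).
#' @param n_samples Spline samples per frame (default 360).
#' @param prev Optional result of `analyze_frame()` for the previous frame;
#'   used to keep the plane normal and the principal axes temporally
#'   consistent (orientation / near-circular tie-breaks).
#' @return One-row tibble: `time_s, maa_mm2, sl_mm, icw_mm, aci, npa_deg,
#'   flag_degenerate, flag_selfintersect`, with the fitted plane, horn and
#'   commissure points attached as attributes `plane`, `horns`,
#'   `commissures`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[1:8]
#' saddle <- cbind(16 * cos(th), 11.2 * sin(th), -2 * cos(2 * th))
#' analyze_frame(saddle)
#' @export
analyze_frame <- function(points, time = 0, n_samples = 360L, prev = NULL) {
  sp <- fit_closed_spline(points, n_samples = n_samples)
  ref_normal <- if (!is.null(prev)) attr(prev, "plane")$normal else c(0, 0, 1)
  pr <- fit_plane_and_project(sp, ref_normal = ref_normal)

  selfx <- FALSE
  maa <- withCallingHandlers(
    spline_area(pr$xy),
    warning = function(w) {
      selfx <<- TRUE
      invokeRestart("muffleWarning")
    }
  )

  prev_axes <- if (!is.null(prev)) attr(prev, "axes") else NULL
  degen <- FALSE
  pa <- withCallingHandlers(
    principal_axes(pr$xy, prev_axes = prev_axes),
    warning = function(w) {
      degen <<- TRUE
      invokeRestart("muffleWarning")
    }
  )

  dims <- compute_dimensions_and_aci(sp$samples, pr$xy, pa$axes)
  junct <- axis_juncture(dims$horns, dims$commissures)
  npa <- compute_npa(dims$horns[1, ], dims$horns[2, ], junct)

  out <- tibble::tibble(
    time_s = time,
    maa_mm2 = as.numeric(maa),
    sl_mm = dims$sl,
    icw_mm = dims$icw,
    aci = dims$aci,
    npa_deg = npa,
    flag_degenerate = degen || pa$degenerate,
    flag_selfintersect = selfx
  )
  attr(out, "plane") <- pr$plane
  attr(out, "axes") <- pa$axes
  attr(out, "horns") <- dims$horns
  attr(out, "commissures") <- dims$commissures
  out
}

#' Per-frame annular geometry for a whole recording
#'
#' Applies [analyze_frame()] to every time sample of a wide crystal-coordinate
#' table, carrying the plane orientation and principal axes forward from frame
#' to frame for temporal stability.
#'
#' @param crystals Data frame with columns `time_s` and `c<k>_x, c<k>_y,
#'   c<k>_z` for crystals `k = 1..n` in circular anatomical order (the layout
#'   written by [write_crystal_csv()] and produced by [simulate_annulus()]).
#' @param n_samples Spline samples per frame.
#' @return Tibble with one row per frame: `time_s, maa_mm2, sl_mm, icw_mm,
#'   aci, npa_deg, flag_degenerate, flag_selfintersect`, of class
#'   `annulus_geometry`.
#' @export
analyze_geometry <- function(crystals, n_samples = 360L) {
  mats <- crystal_matrices(crystals)
  prev <- NULL
  rows <- vector("list", length(mats$frames))
  for (i in seq_along(mats$frames)) {
    prev <- analyze_frame(mats$frames[[i]], time = mats$time[i],
                          n_samples = n_samples, prev = prev)
    rows[[i]] <- prev
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("annulus_geometry", class(out))
  out
}

# split a wide crystal table into a list of n x 3 matrices (one per frame)
crystal_matrices <- function(crystals) {
  crystals <- as.data.frame(crystals)
  if (!"time_s" %in% names(crystals)) stop("`crystals` needs a `time_s` column")
  cc <- grep("^c[0-9]+_[xyz]$", names(crystals), value = TRUE)
  ids <- sort(unique(as.integer(sub("^c([0-9]+)_.*$", "\\1", cc))))
  if (length(ids) < 3L) stop("need coordinate columns c<k>_x/_y/_z for >= 3 crystals")
  need <- as.vector(t(outer(ids, c("x", "y", "z"),
                            function(i, a) paste0("c", i, "_", a))))
  missing_cols <- setdiff(need, names(crystals))
  if (length(missing_cols)) {
    stop("missing crystal coordinate columns: ", paste(missing_cols, collapse = ", "))
  }
  frames <- lapply(seq_len(nrow(crystals)), function(i) {
    matrix(as.numeric(crystals[i, need]), ncol = 3, byrow = TRUE,
           dimnames = list(NULL, c("x", "y", "z")))
  })
  list(time = crystals$time_s, frames = frames)
}

#' @export
autoplot.annulus_geometry <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[, c("time_s", "maa_mm2", "aci", "npa_deg")],
    -"time_s", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Mitral annular geometry through the cardiac cycle")
}

#' Read / write the crystal-coordinate and geometry CSV dialects
#'
#' `read_crystal_csv()` reads a wide table `time_s, c1_x, c1_y, c1_z, ...`
#' (mm); `write_crystal_csv()` writes it. `write_geometry_csv()` writes the
#' per-frame geometry table produced by [analyze_geometry()].
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return A tibble (readers) or `x`, invisibly (writers).
#' @export
read_crystal_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  crystal_matrices(out) # validates layout
  out
}

#' @rdname read_crystal_csv
#' @export
write_crystal_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname read_crystal_csv
#' @export
write_geometry_csv <- function(x, path) {
  readr::write_csv(dplyr::as_tibble(x), path)
  invisible(x)
}
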