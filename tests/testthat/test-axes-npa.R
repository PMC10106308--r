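ellipse_xy <- function(a = 16, b = 11.2, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(a * cos(th), b * sin(th))
}

test_that("principal axes of an ellipse are its geometric axes", {
  pa <- principal_axes(ellipse_xy())
  expect_false(pa$degenerate)
  expect_equal(abs(pa$axes[, 1]), c(1, 0), tolerance = 1e-8)
  expect_equal(abs(pa$axes[, 2]), c(0, 1), tolerance = 1e-8)
  expect_gte(pa$axes[1, 1], 0) # deterministic sign convention
  # right-handed pair
  expect_equal(pa$axes[1, 1] * pa$axes[2, 2] - pa$axes[2, 1] * pa$axes[1, 2],
               1, tolerance = 1e-10)
})

test_that("near-circular projections are flagged degenerate and reuse prior axes", {
  circ <- ellipse_xy(10, 10)
  prev <- matrix(c(0.6, 0.8, -0.8, 0.6), 2)
  expect_warning(pa <- principal_axes(circ, prev_axes = prev), "degenerate")
  expect_true(pa$degenerate)
  expect_equal(pa$axes, prev)
  expect_warning(pa2 <- principal_axes(circ), "degenerate")
  expect_equal(pa2$axes, diag(2))
})

test_that("axis intersections find the horns and commissures", {
  xy <- ellipse_xy()
  s3 <- cbind(xy, -2 * cos(2 * atan2(xy[, 2] / 11.2, xy[, 1] / 16)))
  horns <- axis_intersections(s3, xy, c(0, 1))
  expect_equal(horns$points[1, ], c(0, 11.2, 2), tolerance = 1e-3)
  expect_equal(horns$points[2, ], c(0, -11.2, 2), tolerance = 1e-3)
  comm <- axis_intersections(s3, xy, c(1, 0))
  expect_equal(comm$points[1, ], c(16, 0, -2), tolerance = 1e-3)
  # positive-side point first along the axis
  expect_gt(sum(horns$xy[1, ] * c(0, 1)), 0)
})

test_that("dimensions and circularity index of the canonical saddle", {
  xy <- ellipse_xy()
  s3 <- cbind(xy, -2 * cos(2 * atan2(xy[, 2] / 11.2, xy[, 1] / 16)))
  dims <- compute_dimensions_and_aci(s3, xy, diag(2))
  expect_equal(dims$sl, sqrt(22.4^2), tolerance = 1e-3)   # 2b, horns level
  expect_equal(dims$icw, 32, tolerance = 1e-3)            # 2a
  expect_equal(dims$aci, 0.7, tolerance = 1e-3)
})

test_that("axis juncture reduces to the chord intersection when planar", {
  sl <- rbind(c(0, 5, 0), c(0, -7, 0))
  icw <- rbind(c(9, 0, 0), c(-4, 0, 0))
  expect_equal(axis_juncture(sl, icw), c(0, 0, 0), tolerance = 1e-12)
  # skew chords: midpoint of the common perpendicular
  sl2 <- rbind(c(0, 5, 1), c(0, -5, 1))
  icw2 <- rbind(c(5, 0, -1), c(-5, 0, -1))
  expect_equal(axis_juncture(sl2, icw2), c(0, 0, 0), tolerance = 1e-12)
  expect_error(axis_juncture(sl, sl), "parallel")
})

test_that("NPA closed form: flat ring is 180 degrees, saddle matches 2*atan2(b, h)", {
  expect_equal(compute_npa(c(0, 11.2, 0), c(0, -11.2, 0), c(0, 0, 0)), 180)
  expect_equal(compute_npa(c(0, 11.2, 2), c(0, -11.2, 2), c(0, 0, 0)),
               saddle_npa(11.2, 2), tolerance = 1e-12)
  expect_error(compute_npa(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0)), "coincides")
})

test_that("analyze_frame reproduces the analytic saddle", {
  fr <- analyze_frame(saddle_points(8))
  expect_s3_class(fr, "tbl_df")
  expect_equal(fr$aci, 0.7, tolerance = 1e-3)
  expect_equal(fr$npa_deg, saddle_npa(), tolerance = 0.05)
  expect_equal(fr$maa_mm2, pi * 16 * 11.2, tolerance = 0.005)
  expect_false(fr$flag_degenerate)
  expect_false(fr$flag_selfintersect)
})

test_that("analyze_geometry carries orientation across frames", {
  pts <- saddle_points(8)
  frames <- lapply(seq(0, pi / 3, length.out = 10), function(ang) {
    R <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0), c(-sin(ang), 0, cos(ang)))
    pts %*% t(R)
  })
  wide <- dplyr::bind_rows(lapply(seq_along(frames), function(i) {
    v <- as.vector(t(frames[[i]]))
    names(v) <- as.vector(t(outer(1:8, c("x", "y", "z"),
                                  function(k, a) paste0("c", k, "_", a))))
    tibble::tibble(time_s = (i - 1) * 0.00853, !!!as.list(v))
  }))
  g <- analyze_geometry(wide)
  expect_s3_class(g, "annulus_geometry")
  expect_equal(nrow(g), 10L)
  # a rigidly rotating annulus keeps all its metrics
  expect_lt(diff(range(g$maa_mm2)) / mean(g$maa_mm2), 1e-9)
  expect_lt(diff(range(g$npa_deg)), 1e-7)
})

test_that("crystal table validation names the missing columns", {
  bad <- tibble::tibble(time_s = 0, c1_x = 1, c1_y = 2, c1_z = 3,
                        c2_x = 4, c2_y = 5, c2_z = 6, c3_x = 7, c3_y = 8)
  expect_error(analyze_geometry(bad), "c3_z")
  expect_error(analyze_geometry(tibble::tibble(a = 1)), "time_s")
})
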