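test_that("cyclical reduction matches hand-computed examples", {
  expect_equal(cyclical_reduction(c(650, 600, 550, 620)),
               100 * (650 - 550) / 650, tolerance = 1e-12)
  expect_equal(cyclical_reduction(c(0.72, 0.65, 0.60, 0.70), mode = "absolute"),
               0.12, tolerance = 1e-12)
  expect_equal(cyclical_reduction(c(NA, 10, 8)), 20, tolerance = 1e-12)
  expect_error(cyclical_reduction(NA_real_), "missing")
  expect_error(cyclical_reduction(5), "2 samples")
})

test_that("fractional change matches the hand-computed example", {
  expect_equal(fractional_change(607, 525), 100 * (607 - 525) / 525,
               tolerance = 1e-12)
  expect_equal(fractional_change(c(500, 525, 550), 525),
               c(-100 * 25 / 525, 0, 100 * 25 / 525), tolerance = 1e-12)
  expect_true(all(is.na(fractional_change(c(1, 2), NA))))
  expect_error(fractional_change(10, 0), "positive")
})

test_that("sinusoid deformation velocity equals 2*A*omega/pi", {
  dt <- 0.00853
  t <- seq(0, 2, by = dt)
  A <- 3; f <- 1
  x <- 10 + A * sin(2 * pi * f * t)
  truth <- 2 * A * (2 * pi * f) / pi
  expect_equal(deformation_velocity(x, t), truth, tolerance = 0.02)
})

test_that("linear descent recovers the slope magnitude", {
  t <- seq(0, 0.5, by = 0.00853)
  x <- ifelse(t <= 0.2, 600 - 500 * t, 500 + 400 * (t - 0.2))
  expect_equal(deformation_velocity(x, t), 500, tolerance = 0.005)
})

test_that("monotone-rising beat has undefined deformation velocity", {
  t <- seq(0, 0.4, by = 0.00853)
  expect_warning(v <- deformation_velocity(10 + 5 * t, t), "no descending")
  expect_true(is.na(v))
})

test_that("normalize_beat preserves endpoints and length", {
  t <- seq(0, 0.44, length.out = 53)
  x <- cos(2 * pi * t / 0.44)
  nb <- normalize_beat(x, t, K = 100L)
  expect_equal(nrow(nb), 100L)
  expect_equal(nb$t_norm[c(1, 100)], c(0, 1))
  expect_equal(nb$value[c(1, 100)], x[c(1, 53)])
  expect_error(normalize_beat(x, t, K = 1L), "at least 2")
})

test_that("aggregate_beats averages the first n beats with standard errors", {
  a <- aggregate_beats(c(20, 21, 22, 99))
  expect_equal(a$mean, 21)
  expect_equal(a$se, sd(c(20, 21, 22)) / sqrt(3), tolerance = 1e-12)
  m <- rbind(c(1, 2), c(3, 4), c(5, 6))
  am <- aggregate_beats(m)
  expect_equal(am$mean, c(3, 4))
  expect_equal(am$se, c(2, 2) / sqrt(3), tolerance = 1e-12)
  expect_error(aggregate_beats(c(1, 2)), "at least 3")
})

test_that("segment_beats assigns frames to their ED-to-ED windows", {
  g <- tibble::tibble(time_s = seq(0, 1, by = 0.01), maa_mm2 = 600)
  w <- tibble::tibble(beat = 1:2, t_start = c(0.1, 0.5), t_end = c(0.5, 0.9))
  seg <- segment_beats(g, w)
  expect_true(all(seg$time_s >= 0.1 & seg$time_s < 0.9))
  expect_equal(unique(seg$beat[seg$time_s < 0.5]), 1L)
  expect_equal(unique(seg$beat[seg$time_s >= 0.5]), 2L)
  # short beats are discarded with a warning
  w2 <- tibble::tibble(beat = 1:2, t_start = c(0.1, 0.48), t_end = c(0.48, 0.5))
  expect_warning(seg2 <- segment_beats(g, w2, min_samples = 10L), "discarding")
  expect_false(2L %in% seg2$beat)
  expect_error(segment_beats(g, w[0, ]), "empty")
  w3 <- tibble::tibble(beat = 1L, t_start = 5, t_end = 6)
  expect_error(segment_beats(g, w3), "overlap")
})

test_that("summarize_kinematics recovers the prescribed cycle on clean data", {
  sim <- clean_protocol("baseline", n_beats = 6L, seed = 3)
  w <- detect_ed_es(sim$pressure, sim$pressure$v_lv_ml)
  g <- analyze_geometry(sim$crystals)
  kin <- summarize_kinematics(g, w)
  expect_s3_class(kin, "annulus_kinematics")
  expect_setequal(unique(kin$per_beat$metric), c("maa_mm2", "aci", "npa_deg"))
  truth <- sim$per_beat_geometry
  tmean <- function(m) mean(truth$delta_r[truth$metric == m])
  s <- kin$summary
  expect_equal(s$delta_r_mean[s$metric == "maa_mm2"], tmean("maa_mm2"),
               tolerance = 0.02)
  expect_equal(s$delta_r_mean[s$metric == "aci"], tmean("aci"),
               tolerance = 0.01)
  # curves: K points per beat and metric, fractional change NA only on beat 1
  expect_true(all(table(kin$curves$metric, kin$curves$beat) == 100L))
  first_beat <- min(kin$curves$beat)
  expect_true(all(is.na(kin$curves$frac_change[kin$curves$beat == first_beat])))
  expect_false(anyNA(kin$curves$frac_change[kin$curves$beat != first_beat]))
})
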