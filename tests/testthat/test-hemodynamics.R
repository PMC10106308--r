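test_that("Kelley body surface area", {
  expect_equal(bsa_kelley(58), 734 * 58^0.656 / 1e4, tolerance = 1e-12)
  expect_equal(bsa_kelley(58), 1.053, tolerance = 1e-3)
  expect_error(bsa_kelley(0), "positive")
  expect_error(bsa_kelley(-3), "positive")
})

test_that("two-axis ellipsoid volume", {
  expect_equal(lv_volume_ellipsoid(60, 80), pi / 6 * 60^2 * 80 / 1000,
               tolerance = 1e-12)
  expect_equal(lv_volume_ellipsoid(c(60, 0), c(80, 80))[2], 0)
  expect_error(lv_volume_ellipsoid(-1, 10), "non-negative")
})

test_that("wall-thickness correction interpolates within the beat", {
  ed <- correct_for_wall_thickness(60, 80, wt_ed_mm = 10, wt_es_mm = 14,
                                   wt_apical_mm = 8, phase = 0)
  expect_equal(ed$d_endo_mm, 60 - 20)
  expect_equal(ed$l_endo_mm, 80 - 8)
  es <- correct_for_wall_thickness(60, 80, 10, 14, 8, phase = 1)
  expect_equal(es$wt_mm, 14)
  mid <- correct_for_wall_thickness(60, 80, 10, 14, 8, phase = 0.5)
  expect_equal(mid$wt_mm, 12)
  expect_error(correct_for_wall_thickness(20, 80, 10, 14, 8),
               "non-positive cavity")
})

test_that("ED/ES detection hits the simulator truth within one sample", {
  pv <- simulate_pv(lv_sim_config(n_beats = 8L), seed = 5)
  w <- detect_ed_es(pv$trace, pv$trace$v_lv_ml)
  k <- seq_len(nrow(w))
  expect_true(all(abs(w$i_ed - pv$events$i_ed[k]) <= 1))
  expect_true(all(abs(w$i_es - pv$events$i_es[k]) <= 1))
  expect_true(all(w$t_start < w$t_es & w$t_es < w$t_end))
  expect_false(any(w$flag_corner))
})

test_that("detection rejects unusable pressure input", {
  tt <- seq(0, 2, by = 0.01)
  flat <- tibble::tibble(time_s = tt, p_lv_mmhg = rep(50, length(tt)))
  expect_error(detect_ed_es(flat, rep(100, length(tt))), "flat")
  short <- tibble::tibble(time_s = 1:5 / 100, p_lv_mmhg = 1:5)
  expect_error(detect_ed_es(short, 1:5), "too short")
})

test_that("hemodynamic identities hold per beat", {
  pv <- simulate_pv(lv_sim_config(n_beats = 6L), seed = 6)
  w <- detect_ed_es(pv$trace, pv$trace$v_lv_ml)
  h <- summarize_hemodynamics(pv$trace, pv$trace$v_lv_ml, w, bw_kg = 58)
  pb <- h$per_beat
  expect_equal(pb$sv_ml, pb$edv_ml - pb$esv_ml, tolerance = 1e-12)
  expect_equal(pb$ef_pct, 100 * pb$sv_ml / pb$edv_ml, tolerance = 1e-12)
  expect_equal(pb$ci, pb$hr_bpm * pb$sv_ml / (1000 * h$bsa_m2),
               tolerance = 1e-12)
  expect_equal(pb$edv_i, pb$edv_ml / h$bsa_m2, tolerance = 1e-12)
  # against the generator ground truth
  truth <- pv$per_beat[seq_len(nrow(pb)), ]
  expect_equal(pb$edv_ml, truth$edv_ml, tolerance = 0.01)
  expect_equal(pb$esv_ml, truth$esv_ml, tolerance = 0.01)
  expect_equal(pb$spmax_mmhg, truth$spmax_mmhg, tolerance = 0.01)
  expect_false(any(pb$flag_nonejecting))
})

test_that("state measurement beats: 20% EDP drop (ICC) and SPmax plateau (AO)", {
  pb <- tibble::tibble(beat = 1:5, edp_mmhg = c(9.8, 8.9, 8.1, 7.5, 6.9),
                       spmax_mmhg = c(160, 185, 200, 203, 204))
  expect_equal(select_state_beat(pb, "icc", baseline_edp = 9.8), 4L)
  expect_equal(select_state_beat(pb, "ao"), 4L)
  expect_error(select_state_beat(pb, "icc"), "baseline_edp")
  expect_error(select_state_beat(pb[1:2, ], "icc", baseline_edp = 9.8),
               "20%")
  expect_error(select_state_beat(tibble::tibble(
    beat = 1:3, spmax_mmhg = c(100, 150, 200)), "ao"), "plateau")
})

test_that("ESPVR fit recovers an exact line to machine precision", {
  esv <- seq(76, 50, length.out = 8)
  pb <- tibble::tibble(esv_ml = esv, esp_mmhg = 2.66 * (esv - 15))
  fit <- suppressWarnings(estimate_ees(pb))
  expect_s3_class(fit, "ees_fit")
  expect_equal(fit$slope, 2.66, tolerance = 1e-12)
  expect_equal(fit$v0_ml, 15, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(estimate_ees(pb[1:2, ]), "at least 3")
  expect_error(estimate_ees(tibble::tibble(esv_ml = rep(60, 5),
                                           esp_mmhg = 1:5)), "do not vary")
  # max_beats truncates from the start of the run
  fit10 <- suppressWarnings(estimate_ees(pb, max_beats = 4L))
  expect_equal(fit10$n_beats, 4L)
})

test_that("tidy and glance methods return broom-shaped tibbles", {
  esv <- seq(76, 50, length.out = 8)
  pb <- tibble::tibble(esv_ml = esv,
                       esp_mmhg = 2.66 * (esv - 15) + rnorm(8, 0, 0.5))
  fit <- estimate_ees(pb)
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate[td$term == "ees_mmhg_ml"], fit$slope)
  gl <- generics::glance(fit)
  expect_equal(gl$nobs, 8L)
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)
})

test_that("pressure CSV reader validates the dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(time_s = c(0, 0.01),
                                  p_lv_mmhg = c(10, 11)), path)
  expect_named(read_pressure_csv(path), c("time_s", "p_lv_mmhg"))
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(t = 1, p = 2), bad)
  expect_error(read_pressure_csv(bad), "p_lv_mmhg")
})
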