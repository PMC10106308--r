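test_that("annulus simulator truth matches its own closed forms", {
  sim <- simulate_annulus(annulus_sim_config(noise_sd_mm = 0, rot_deg = 0,
                                             trans_mm = 0, n_beats = 2L),
                          seed = 1)
  tr <- sim$truth
  expect_equal(tr$maa_mm2, pi * tr$a_mm * tr$b_mm, tolerance = 1e-12)
  expect_equal(tr$aci, tr$b_mm / tr$a_mm, tolerance = 1e-12)
  expect_equal(tr$npa_deg, 2 * atan2(tr$b_mm, tr$h_mm) * 180 / pi,
               tolerance = 1e-12)
  # extrema hit the configured maxima at end-diastole
  cf <- sim$config
  expect_equal(max(tr$maa_mm2), cf$maa_max_mm2, tolerance = 1e-10)
  expect_equal(max(tr$aci), cf$aci_max, tolerance = 1e-10)
  expect_equal(max(tr$npa_deg), cf$npa_max_deg, tolerance = 1e-10)
  # the sample grid need not land exactly on end-systole
  expect_equal(min(tr$maa_mm2), cf$maa_max_mm2 * (1 - cf$d_maa),
               tolerance = 1e-4)
})

test_that("crystal table layout and determinism", {
  cfg <- annulus_sim_config(n_beats = 2L)
  a <- simulate_annulus(cfg, seed = 9)
  b <- simulate_annulus(cfg, seed = 9)
  expect_identical(a$crystals, b$crystals)
  expect_named(a$crystals,
               c("time_s", as.vector(t(outer(1:8, c("x", "y", "z"),
                                             function(i, s) paste0("c", i, "_", s))))))
  c_ <- simulate_annulus(cfg, seed = 10)
  expect_false(identical(a$crystals, c_$crystals))
  # noiseless frame 1 is the canonical saddle: crystal 3 on the +SL horn
  clean <- simulate_annulus(annulus_sim_config(noise_sd_mm = 0, rot_deg = 0,
                                               trans_mm = 0, n_beats = 2L))
  expect_equal(clean$crystals$c3_x[1], 0, tolerance = 1e-9)
  expect_gt(clean$crystals$c3_z[1], 0) # horns high
  expect_lt(clean$crystals$c1_z[1], 0) # commissures low
})

test_that("elastance ventricle honors its prescribed volumes and pressures", {
  pv <- simulate_pv(lv_sim_config(n_beats = 4L))
  cf <- pv$config
  pb <- pv$per_beat
  expect_equal(pb$edv_ml, rep(cf$edv_ml, 4), tolerance = 1e-9)
  expect_equal(pb$sv_ml, rep(44, 4), tolerance = 1e-9)
  # end-systolic pressure obeys ESP = Emax (ESV - V0) exactly
  expect_equal(pb$esp_mmhg, cf$e_max * (pb$esv_ml - cf$v0_ml),
               tolerance = 1e-9)
  # trace is physiological: positive pressures, volume within [ESV, EDV]
  expect_true(all(pv$trace$p_lv_mmhg > 0))
  expect_true(all(pv$trace$v_lv_ml <= cf$edv_ml + 1e-9))
  expect_true(all(pv$trace$v_lv_ml >= min(pb$esv_ml) - 1e-9))
})

test_that("ICC protocol: preload falls, EDP declines monotonically", {
  icc <- clean_protocol("icc", n_beats = 10L, seed = 2)
  pb <- icc$per_beat_hemo
  expect_true(all(diff(pb$edv_ml) < 0))
  expect_true(all(diff(pb$edp_mmhg) < 0))
  expect_lte(pb$edp_mmhg[10], 0.8 * pb$edp_mmhg[1])
  # ESPVR stays on one line: slope of truth points equals e_max
  fit <- suppressWarnings(estimate_ees(pb))
  expect_equal(fit$slope, icc$configs$lv$e_max, tolerance = 1e-9)
  expect_equal(fit$v0_ml, icc$configs$lv$v0_ml, tolerance = 1e-7)
  # the annular area shrinks with the ventricle
  tr <- icc$per_beat_geometry
  maa_ed <- tr$value_ed[tr$metric == "maa_mm2"]
  expect_true(all(diff(maa_ed) < 0))
})

test_that("AO protocol: afterload rises to a plateau, saddle flattens", {
  ao <- clean_protocol("ao", n_beats = 20L, seed = 3)
  pb <- ao$per_beat_hemo
  expect_gt(pb$esp_mmhg[20], pb$esp_mmhg[1] * 1.05)
  rel <- abs(diff(pb$spmax_mmhg)) / pb$spmax_mmhg[-1]
  expect_true(any(rel[1:19] < 0.02)) # plateau within 20 beats
  tr <- ao$per_beat_geometry
  npa_ed <- tr$value_ed[tr$metric == "npa_deg"]
  expect_gt(npa_ed[20], npa_ed[1]) # flatter annulus at full occlusion
})

test_that("protocol dataset shares one clock between annulus and ventricle", {
  sim <- clean_protocol("baseline", n_beats = 3L, seed = 4)
  expect_equal(sim$crystals$time_s, sim$pressure$time_s)
  expect_equal(nrow(sim$crystals), nrow(sim$pressure))
  expect_identical(sim$protocol, "baseline")
})

test_that("written dataset round-trips through the CSV readers", {
  sim <- clean_protocol("baseline", n_beats = 2L, seed = 5)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("crystals.csv", "pressure.csv",
                                               "truth.json")))))
  cr <- read_crystal_csv(file.path(dir, "crystals.csv"))
  pr <- read_pressure_csv(file.path(dir, "pressure.csv"))
  expect_equal(as.data.frame(cr), as.data.frame(sim$crystals),
               tolerance = 1e-9)
  expect_equal(pr$p_lv_mmhg, sim$pressure$p_lv_mmhg, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$protocol, "baseline")
})
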