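test_that("fixture gaits are seeded and deterministic", {
  t1 <- make_fixture_gait(seed = 10, noise_sd = 2)
  t2 <- make_fixture_gait(seed = 10, noise_sd = 2)
  expect_identical(t1, t2)
  t3 <- make_fixture_gait(seed = 11, noise_sd = 2)
  expect_false(identical(t1$grf, t3$grf))
})

test_that("gait metrics recover the fixture parameters", {
  tr <- make_fixture_gait(seed = 1, cycle = 0.72, duty_factor = 0.65,
                          speed = 1.0, n_strides = 10)
  sm <- gait_metrics(tr)
  expect_equal(sm$cycle_duration, 0.72, tolerance = 0.01)
  expect_equal(sm$duty_factor, 0.65, tolerance = 0.01)
  expect_equal(sm$speed, 1.0, tolerance = 0.01)
  # constant-velocity COM: stride length = v * T
  expect_equal(sm$stride_length, 0.72, tolerance = 0.01)
  expect_equal(sm$speed, sm$stride_length / sm$cycle_duration,
               tolerance = 0.02)
  # a different parameterization is recovered too
  tr2 <- make_fixture_gait(seed = 2, cycle = 0.6, duty_factor = 0.7,
                           speed = 0.8, n_strides = 10)
  sm2 <- gait_metrics(tr2)
  expect_equal(sm2$cycle_duration, 0.6, tolerance = 0.01)
  expect_equal(sm2$duty_factor, 0.7, tolerance = 0.01)
  expect_equal(sm2$speed, 0.8, tolerance = 0.01)
  # too few strides raises the insufficient-data error
  short <- make_fixture_gait(seed = 3, n_strides = 3)
  expect_error(gait_metrics(short), "insufficient")
})

test_that("GRF profile classification separates single and double peaks", {
  single <- make_fixture_gait(seed = 4, grf_shape = "single", n_strides = 8)
  expect_identical(classify_grf_profile(single)$profile, "single")
  double <- make_fixture_gait(seed = 4, grf_shape = "double", n_strides = 8)
  cls <- classify_grf_profile(double)
  expect_identical(cls$profile, "double")
  expect_gte(cls$n_peaks, 2L)
  # flat zero trace: an error-free "none" marker
  flat <- single
  flat$grf[, ] <- 0
  flat$events <- flat$events[0, ]
  expect_identical(classify_grf_profile(flat)$profile, "none")
})

test_that("trial CSV round-trip preserves metrics", {
  tr <- make_fixture_gait(seed = 5, n_strides = 8)
  path <- tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  tr2 <- read_trial_csv(path)
  sm1 <- gait_metrics(tr)
  sm2 <- gait_metrics(tr2)
  for (f in c("cycle_duration", "stride_length", "speed", "duty_factor",
              "percent_recovery"))
    expect_equal(sm2[[f]], sm1[[f]], tolerance = 1e-9, info = f)
  expect_equal(tr2$distance, tr$distance, tolerance = 1e-12)
  expect_equal(tr2$work_pos, tr$work_pos)
  expect_equal(tr2$events$time, tr$events$time)
  unlink(path); unlink(sub("\\.csv$", "_events.csv", path))
})

test_that("simulated trials round-trip through CSV as well", {
  tr <- simulate_gait(the_model, cpg_controller(crafted_genome()),
                      duration = 0.5, on_nonfinite = "fall",
                      options = macaquegait:::.sim_options(stop_on_fall = FALSE))
  path <- tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  tr2 <- read_trial_csv(path)
  expect_equal(tr2$q, tr$q, tolerance = 1e-12)
  expect_equal(tr2$grf, tr$grf, tolerance = 1e-12)
  expect_equal(tr2$f_pe, tr$f_pe, tolerance = 1e-12)
  expect_equal(tr2$jgrf_brake, tr$jgrf_brake, tolerance = 1e-12)
  unlink(path); unlink(sub("\\.csv$", "_events.csv", path))
})

test_that("morph pipeline runs a degenerate schedule and is resumable", {
  m <- the_model
  cfg <- ga_config(population = 4, generations = 1, duration = 1.2)
  out <- tempfile("morph")
  mr <- run_morph_experiment(m, cfg, schedule = c(0, 0.036), seed = 3,
                             out_dir = out)
  expect_equal(nrow(mr$summary), 2)
  expect_equal(mr$summary$heel_drop, c(0, 0.036))
  expect_length(mr$genomes, 2)
  # tiny budget: steps are recorded as failed, not crashed
  expect_true(all(!mr$summary$success))
  expect_true(all(is.na(mr$summary$cot)))
  # resuming re-loads identical genomes without re-optimizing
  mr2 <- run_morph_experiment(m, cfg, schedule = c(0, 0.036), seed = 999,
                              out_dir = out)
  expect_identical(round(mr2$genomes[[1]], 10), round(mr$genomes[[1]], 10))
  expect_identical(round(mr2$genomes[[2]], 10), round(mr$genomes[[2]], 10))
  expect_error(run_morph_experiment(m, cfg, schedule = c(0.01, 0.005)))
  unlink(out, recursive = TRUE)
})
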