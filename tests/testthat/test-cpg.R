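test_that("oscillators advance at omega when anti-phase", {
  p <- cpg_params()
  expect_equal(p$omega, 2 * pi / 0.747)
  ph <- oscillator_step(p, phi_R = 1 + pi, phi_L = 1, dt = 1e-3)
  expect_equal(unname(ph["phi_R"] - (1 + pi)), p$omega * 1e-3)
  expect_equal(unname(ph["phi_L"] - 1), p$omega * 1e-3)
  # dt = 0 leaves phases unchanged
  expect_equal(unname(oscillator_step(p, 2, 1, 0)), c(2, 1))
})

test_that("phase difference converges to anti-phase from any offset", {
  p <- cpg_params()
  for (offset in c(0.3, 2, 5)) {
    phi <- c(offset, 0)
    for (i in 1:20000) phi <- unname(oscillator_step(p, phi[1], phi[2], 1e-3))
    d <- (phi[1] - phi[2]) %% (2 * pi)
    expect_equal(d, pi, tolerance = 0.02)
  }
})

test_that("touchdown resets only the touching leg's phase", {
  ph <- c(phi_R = 5.9, phi_L = 2.2)
  expect_equal(unname(reset_phase(ph, "R")), c(0, 2.2))
  expect_equal(unname(reset_phase(ph, "L")), c(5.9, 0))
  expect_equal(unname(reset_phase(ph, c("R", "L"))), c(0, 0))
  expect_equal(reset_phase(ph, character(0)), ph)
})

test_that("pattern activation normalizes to delta and handles mixtures", {
  grid <- 2 * pi * (0:2047) / 2048
  pat <- list(gamma = 0.7, delta = 0.43, mu1 = 2, mu2 = 5,
              sigma1 = 0.3, sigma2 = 0.5)
  a <- pattern_activation(pat, grid)
  expect_equal(max(a), 0.43)
  # gamma = 1: single bell peaking at mu1
  pat1 <- list(gamma = 1, delta = 1, mu1 = 1.5, mu2 = 4, sigma1 = 0.2,
               sigma2 = 0.2)
  a1 <- pattern_activation(pat1, grid)
  expect_equal(grid[which.max(a1)], 1.5, tolerance = 0.01)
  # equal mixture with equal widths is symmetric between the two peaks
  pat2 <- list(gamma = 0.5, delta = 1, mu1 = 1, mu2 = 4, sigma1 = 0.2,
               sigma2 = 0.2)
  expect_equal(pattern_activation(pat2, 1), pattern_activation(pat2, 4),
               tolerance = 1e-9)
  # 2pi-periodicity under the periodic extension
  expect_lt(abs(pattern_activation(pat, 0) -
                  pattern_activation(pat, 2 * pi - 1e-12)), 1e-9)
  expect_error(pattern_activation(list(gamma = 1, delta = 1, mu1 = 1,
                                       mu2 = 1, sigma1 = -1, sigma2 = 1), 0),
               "sigma")
})

test_that("controller output applies posture feedback to support legs only", {
  ctrl <- cpg_controller(crafted_genome(), kappa = 5, theta_ref = 0.3)
  # at the reference pitch: no correction
  a0 <- controller_output(ctrl, c(0.5, 3.6), pitch = 0.3,
                          grf_vert = c(50, 50))
  a_none <- controller_output(ctrl, c(0.5, 3.6), pitch = 0.3,
                              grf_vert = c(0, 0))
  expect_equal(a0, a_none)
  # pitch 0.1 rad below reference: IL of support legs gets +0.5
  a1 <- controller_output(ctrl, c(0.5, 3.6), pitch = 0.2,
                          grf_vert = c(50, 0))
  expect_equal(unname(a1["IL_R"] - a_none["IL_R"]), 0.5)
  expect_equal(unname(a1["IL_L"]), unname(a_none["IL_L"]))  # swing leg
  expect_equal(unname(a1["GMED_R"]), unname(a_none["GMED_R"]))
  # pitch above reference drives GMED instead
  a2 <- controller_output(ctrl, c(0.5, 3.6), pitch = 0.4,
                          grf_vert = c(50, 50))
  expect_equal(unname(a2["GMED_R"] - a_none["GMED_R"]), 0.5)
  expect_error(controller_output(ctrl, c(0, 0), NaN, c(0, 0)), "finite")
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("in-loop controller matches the R mirror on recorded samples", {
  m <- the_model
  ctrl <- cpg_controller(crafted_genome(), ramp_time = 0)
  tr <- simulate_gait(m, ctrl, duration = 0.6, record_dt = 1e-3,
                      options = macaquegait:::.sim_options(stop_on_fall = FALSE))
  for (i in seq(1, length(tr$time), by = 23)) {
    a <- controller_output(ctrl, tr$phases[i, ], tr$q[i, "pitch"],
                           tr$grf[i, c("vert_R", "vert_L")])
    expect_equal(unname(tr$act[i, ]), unname(a), tolerance = 1e-9)
  }
})

test_that("all emitted activations stay in [0, 1] through a trial", {
  tr <- simulate_gait(the_model, cpg_controller(crafted_genome()),
                      duration = 2, on_nonfinite = "fall",
                      options = macaquegait:::.sim_options(stop_on_fall = FALSE))
  expect_true(all(tr$act >= 0 & tr$act <= 1))
})

test_that("genome serialization round-trips", {
  g <- crafted_genome()
  pat <- genome_to_patterns(g)
  expect_equal(patterns_to_genome(pat), g)
  path <- tempfile(fileext = ".txt")
  write_genome(g, path)
  expect_equal(read_genome(path), g, tolerance = 1e-15)
  unlink(path)
})
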