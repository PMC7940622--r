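test_that("default model reproduces the published constants", {
  m <- the_model
  segs <- m$segments
  expect_equal(segs$mass[segs$name == "HAT"], 8.184)
  expect_equal(segs$length[segs$name == "thigh"], 0.163)
  expect_equal(segs$length[segs$name == "foot"], 0.074)
  expect_equal(segs$moment_of_inertia,
               c(2.07e-2, 1.61e-3, 7.01e-4, 5.49e-5, 6.26e-6))
  expect_equal(total_mass(m), 8.184 + 2 * (0.557 + 0.269 + 0.080 + 0.021))
  expect_equal(m$joints$viscous_coefficient, c(0.109, 0.317, 0.0943, 0.01))
  expect_equal(unlist(m$knee_stop), c(k1 = 1, k2 = 30, k3 = -0.23))
  expect_equal(m$pe_params$k1_pe, 26)
  expect_equal(m$pe_params$k2_pe, 150)
  expect_equal(unlist(m$contact$params[c("k_vert", "c_vert", "k_horz",
                                         "c_horz")]),
               c(k_vert = 6000, c_vert = 60, k_horz = 1200, c_horz = 13))
  fmax <- vapply(m$muscles, `[[`, 0, "f_max")
  expect_equal(fmax, c(642, 738, 2514, 390, 822, 720, 804, 720, 140, 180))
  expect_identical(vapply(m$muscles, `[[`, "", "name"),
                   c("IL", "GMED", "VAS", "TA", "SOL",
                     "RF", "BIFl", "GAS", "EDL", "FDL"))
  expect_length(validate_model(m), 0)
})

test_that("rest-length calibration matches an independent polyline oracle", {
  m <- the_model
  for (mus in m$muscles) {
    L <- oracle_muscle_length(m, mus$rest_posture * pi / 180, mus$name)
    expect_equal(mus$rest_length, L, tolerance = 1e-12)
    # PE force is exactly zero at the calibration posture
    expect_equal(pe_force(m, mus$rest_length, mus$rest_length), 0)
  }
})

test_that("muscle_length agrees with the oracle at random postures", {
  m <- the_model
  set.seed(7)
  r <- m$joint_ranges
  for (i in 1:25) {
    q <- c(hip = runif(1, r$hip[1], r$hip[2]),
           knee = runif(1, r$knee[1], r$knee[2]),
           ankle = runif(1, r$ankle[1], r$ankle[2]),
           mp = runif(1, r$mp[1], r$mp[2]))
    for (mn in c("IL", "VAS", "SOL", "GAS", "RF", "FDL"))
      expect_equal(muscle_length(m, q, mn), oracle_muscle_length(m, q, mn),
                   tolerance = 1e-10)
  }
})

test_that("moment arm equals the negative length gradient (finite diff)", {
  m <- the_model
  set.seed(8)
  r <- m$joint_ranges
  h <- 1e-6
  for (i in 1:15) {
    q <- c(hip = runif(1, r$hip[1], r$hip[2]),
           knee = runif(1, r$knee[1], r$knee[2]),
           ankle = runif(1, r$ankle[1], r$ankle[2]),
           mp = runif(1, r$mp[1], r$mp[2]))
    for (mus in m$muscles) {
      for (j in mus$spanned_joints) {
        qp <- q; qp[j] <- qp[j] + h
        qm <- q; qm[j] <- qm[j] - h
        fd <- -(muscle_length(m, qp, mus$name) -
                  muscle_length(m, qm, mus$name)) / (2 * h)
        expect_equal(moment_arm(m, q, mus$name, j), fd, tolerance = 1e-6)
      }
    }
  }
})

test_that("moment-arm signs match anatomical actions over the joint ranges", {
  m <- the_model
  action <- list(IL = c(hip = 1), GMED = c(hip = -1), VAS = c(knee = 1),
                 TA = c(ankle = 1), SOL = c(ankle = -1),
                 RF = c(hip = 1, knee = 1), BIFl = c(hip = -1, knee = -1),
                 GAS = c(knee = -1, ankle = -1), EDL = c(ankle = 1, mp = 1),
                 FDL = c(ankle = -1, mp = -1))
  r <- m$joint_ranges
  grid <- expand.grid(hip = seq(r$hip[1], r$hip[2], length.out = 5),
                      knee = seq(r$knee[1], r$knee[2], length.out = 5),
                      ankle = seq(r$ankle[1], r$ankle[2], length.out = 5),
                      mp = seq(r$mp[1], r$mp[2], length.out = 5))
  for (mn in names(action)) {
    for (j in names(action[[mn]])) {
      ma <- apply(grid, 1, function(g) moment_arm(m, unlist(g), mn, j))
      expect_true(all(sign(ma) == action[[mn]][[j]]),
                  info = paste(mn, j))
      # magnitudes a plausible fraction of the spanned segment length
      expect_lt(max(abs(ma)), 0.25 * 0.182)
    }
  }
  # joint not spanned by a muscle contributes a zero moment arm
  expect_identical(moment_arm(m, c(hip = 0.5), "VAS", "hip"), 0)
  expect_identical(moment_arm(m, c(hip = 0.5), "SOL", "mp"), 0)
})

test_that("heel translation morphs only the heel contact coordinate", {
  m <- the_model
  expect_identical(apply_heel_translation(m, 0), m)
  m36 <- apply_heel_translation(m, 0.036)
  hi <- m$contact$heel_index
  expect_equal(m36$contact$layout$y[hi], m$contact$layout$y[hi] - 0.036)
  expect_equal(m36$contact$layout$y[-hi], m$contact$layout$y[-hi])
  expect_equal(m36$contact$layout$x, m$contact$layout$x)
  expect_equal(m36$contact$heel_drop, 0.036)
  expect_equal(m36$segments, m$segments)
  expect_equal(m36$muscles, m$muscles)
  expect_equal(total_mass(m36), total_mass(m))
  # absolute, not cumulative: re-morphing a morphed model
  m10a <- apply_heel_translation(m, 0.010)
  m10b <- apply_heel_translation(apply_heel_translation(m, 0.025), 0.010)
  expect_equal(m10a$contact$layout, m10b$contact$layout)
  expect_error(apply_heel_translation(m, -0.001), "heel drop")
  expect_error(apply_heel_translation(m, 0.037), "heel drop")
  expect_silent(apply_heel_translation(m, 0.05, max_drop = 0.05))
})

test_that("validate_model flags violated invariants", {
  m <- the_model
  m$segments$mass[2] <- -1
  expect_true(any(grepl("mass > 0", validate_model(m))))
  m2 <- the_model
  m2$contact$layout$x[m2$contact$heel_index] <- 0.05
  expect_true(any(grepl("most posterior", validate_model(m2))))
})

test_that("model config YAML round-trips losslessly", {
  m <- the_model
  path <- tempfile(fileext = ".yaml")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_equal(m2$segments, m$segments)
  expect_equal(m2$joints, m$joints)
  expect_equal(m2$contact$layout, m$contact$layout)
  expect_equal(m2$pe_params[c("k1_pe", "k2_pe")],
               m$pe_params[c("k1_pe", "k2_pe")])
  for (i in seq_along(m$muscles)) {
    expect_equal(m2$muscles[[i]]$path, m$muscles[[i]]$path)
    expect_equal(m2$muscles[[i]]$rest_length, m$muscles[[i]]$rest_length)
  }
  unlink(path)
})
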