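test_that("the frozen calibration reproduces every reference yield", {
  p <- sim_params()
  anchors <- ivt_reference_reactions()
  pred <- ivt_yield_mean(anchors, p)
  expect_true(all(abs(pred - anchors$yield_gL) <= anchors$sd_gL))
  expect_lte(sqrt(mean((pred - anchors$yield_gL)^2)), mean(anchors$sd_gL))
})

test_that("the benchmark reaction is outperformed by every optimized one", {
  p <- sim_params()
  pred <- ivt_yield_mean(ivt_reference_reactions(), p)
  expect_true(all(pred[1:6] > pred[7]))
})

test_that("yields stay within [0, Y_max] across the whole space", {
  p <- sim_params()
  cond <- random_conditions(ivt_space(), 500, seed = 31)
  y <- ivt_yield_mean(cond, p)
  expect_true(all(y >= 0 & y <= p$y_max))
})

test_that("the surface is continuous in the real parameters", {
  p <- sim_params()
  base <- ivt_reference_reactions()[3, ]
  y0 <- ivt_yield_mean(base, p)
  for (nm in c("cofactor_mM", "DTT_mM", "NTPs_mM", "spermidine_mM", "pH")) {
    bumped <- base
    bumped[[nm]] <- bumped[[nm]] + 1e-9
    expect_equal(ivt_yield_mean(bumped, p), y0, tolerance = 1e-6)
  }
})

test_that("the calibrated optimum sits in the published windows", {
  p <- sim_params()
  # dense random search over the space for the argmax
  cond <- random_conditions(ivt_space(), 20000, seed = 32)
  best <- cond[which.max(ivt_yield_mean(cond, p)), ]
  expect_lt(best$pH, 7.5)
  f <- p$factors
  expect_gte(f$pH$center, 6.5); expect_lte(f$pH$center, 7.2)
  expect_gte(f$cofactor_mM$center, 40); expect_lte(f$cofactor_mM$center, 60)
  expect_gte(f$spermidine_mM$center, 1); expect_lte(f$spermidine_mM$center, 3)
  expect_gte(10^f$T7_UmL$center, 6000 * (1 - 1e-9))
  expect_lte(10^f$T7_UmL$center, 8000 * (1 + 1e-9))
})

test_that("measurements add truncated Gaussian replicate noise", {
  p <- sim_params()
  cond <- ivt_reference_reactions()[2, ]
  exact <- ivt_measure(cond, p, noise_sd = 0)
  expect_equal(exact$yield_gL, ivt_yield_mean(cond, p))

  many <- ivt_measure(cond[rep(1, 1000), ], p, seed = 33, noise_sd = 0.5)
  expect_equal(sd(many$yield_gL), 0.5, tolerance = 0.1 * 0.5)
  expect_true(all(many$yield_gL >= 0))

  low <- dplyr::mutate(cond, cofactor_mM = 0.5, NTPs_mM = 1)
  draws <- ivt_measure(low[rep(1, 500), ], p, seed = 34, noise_sd = 1)
  expect_true(all(draws$yield_gL >= 0)) # truncation at zero

  a <- ivt_measure(cond, p, seed = 35)
  b <- ivt_measure(cond, p, seed = 35)
  expect_identical(a, b)
})

test_that("base-template kinetics saturate with the calibrated rate", {
  p <- sim_params()
  r5 <- ivt_reference_reactions()[5, ]
  prof <- ivt_kinetic_profile(r5, p, times = seq(0, 300, by = 1))
  expect_equal(prof$mrna_gL[1], 0) # nothing at t = 0
  expect_true(all(diff(prof$mrna_gL) >= 0))

  m120 <- prof$mrna_gL[prof$time_min == 120]
  expect_equal(m120, 10.65, tolerance = 0.1)
  plateau <- ivtbo:::plateau_surface(r5, p) * p$kinetics$kinetic_scale
  expect_equal(m120 / plateau, 0.80, tolerance = 1e-6)

  expect_true(all(diff(prof$dsrna_ratio) >= 0))
  expect_true(all(prof$dsrna_ratio <= p$kinetics$dsrna_asymptote + 1e-12))
  expect_equal(prof$dsrna_ratio[prof$time_min == 300], 0.05,
               tolerance = 0.003)
  expect_true(all(prof$dsrna_ratio[prof$time_min <= 115] == 0))
})

test_that("long templates decline after the two-hour peak", {
  p <- sim_params()
  r5 <- ivt_reference_reactions()[5, ]
  prof <- ivt_kinetic_profile(r5, p, times = c(120, 145, 300),
                              template_bp = 5299)
  expect_equal(prof$mrna_gL[prof$time_min == 145], 9.7, tolerance = 0.29)
  expect_equal(prof$mrna_gL[prof$time_min == 300], 7.1, tolerance = 0.19)
  expect_lt(prof$mrna_gL[3], prof$mrna_gL[2])

  # the base template is below the decline threshold and unaffected
  base <- ivt_kinetic_profile(r5, p, times = c(120, 300))
  expect_gt(base$mrna_gL[2], base$mrna_gL[1])

  expect_error(ivt_kinetic_profile(r5, p, times = c(-5, 10)),
               "non-negative")
  expect_error(ivt_kinetic_profile(r5, p, times = c(10, 400)), "300")
})

test_that("recalibration from the anchors reproduces the frozen surface", {
  anchors <- ivt_reference_reactions()
  p <- calibrate_simulator(anchors, seed = 1, restarts = 3)
  expect_s3_class(p, "ivt_sim_params")
  pred <- ivt_yield_mean(anchors, p)
  expect_true(all(abs(pred - anchors$yield_gL) <= anchors$sd_gL))
  expect_lte(attr(p, "rmse"), mean(anchors$sd_gL))
  # kinetic anchors are solved in closed form, identically every time
  expect_equal(p$kinetics$k, log(5) / 120, tolerance = 1e-12)
  r5 <- anchors[5, ]
  expect_equal(ivt_kinetic_profile(r5, p, times = 120)$mrna_gL, 10.65,
               tolerance = 1e-6)
})

test_that("the params fixture validates and round-trips", {
  p <- sim_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_params(p, path)
  p2 <- sim_params(path)
  anchors <- ivt_reference_reactions()
  expect_equal(ivt_yield_mean(anchors, p2), ivt_yield_mean(anchors, p),
               tolerance = 1e-12)
})
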