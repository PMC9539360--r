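# cheap knobs for loop tests: small pools and few restarts keep the
# mathematical contract while running in seconds
fast <- list(restarts = 2, maxit = 40, pool_size = 1500, n_local = 200)

test_that("initialization delegates to the Latin hypercube design", {
  d <- initialize_design(ivt_space(), seed = 1)
  expect_equal(nrow(d), 16)
  expect_true(all(d$source == "lhs"))
  expect_true(all(d$batch_id == 0L))
  expect_identical(initialize_design(ivt_space(), seed = 1), d)

  d4 <- initialize_design(ivt_space(), n_init = 4, seed = 2)
  expect_equal(nrow(d4), 4)
  expect_equal(nrow(validate_conditions(d4[ivt_space()$specs$name])), 0)
})

test_that("recording appends immutably and rejects bad input", {
  s <- ivt_space()
  log <- empty_experiment_log(s)
  d <- initialize_design(s, n_init = 4, seed = 3)
  log <- record_results(log, d, c(1, 2, 3, 4), space = s)
  expect_equal(nrow(log), 4)

  before <- log
  d2 <- initialize_design(s, n_init = 4, seed = 4)
  log2 <- record_results(log, d2, c(5, 6, 7, 8), space = s)
  expect_equal(nrow(log2), 8)
  expect_identical(log2[1:4, ], before) # prior entries untouched

  expect_error(record_results(log, d2, c(1, 2)), "2 yields for 4")
  expect_error(record_results(log, d2, c(1, 2, 3, -1)), "non-negative")

  # partial batches: NA yields are reactions not yet performed
  log3 <- record_results(log, d2, c(5, NA, 7, NA), space = s)
  expect_equal(nrow(log3), 6)
})

test_that("a step refits, proposes a valid batch and leaves the log alone", {
  s <- ivt_space()
  sim <- sim_params()
  d <- initialize_design(s, n_init = 10, seed = 5)
  obs <- ivt_measure(d[s$specs$name], sim, seed = 6, noise_sd = 0.5)
  log <- record_results(empty_experiment_log(s), d, obs$yield_gL, space = s)
  digest <- log

  prop <- bo_step(log, s, batch_size = 4, seed = 7, restarts = fast$restarts,
                  maxit = fast$maxit, pool_size = fast$pool_size,
                  n_local = fast$n_local)
  expect_equal(nrow(prop), 4)
  expect_true(all(prop$source == "bo"))
  expect_true(all(prop$batch_id == 1L))
  expect_equal(nrow(validate_conditions(prop[s$specs$name], s)), 0)
  expect_identical(log, digest)

  prop2 <- bo_step(log, s, batch_size = 4, seed = 7,
                   restarts = fast$restarts, maxit = fast$maxit,
                   pool_size = fast$pool_size, n_local = fast$n_local)
  expect_identical(prop, prop2)

  expect_error(bo_step(empty_experiment_log(s), s), "at least 2")
})

test_that("stopping triggers on budget and on plateau", {
  s <- ivt_space()
  base <- initialize_design(s, n_init = 10, seed = 8)[rep(1, 150), ]
  log <- record_results(empty_experiment_log(s), base,
                        rep(5, 150), space = s)
  dec <- stopped(log, stopping_rule())
  expect_true(dec$stop)
  expect_equal(dec$reason, "budget")

  flat <- record_results(empty_experiment_log(s), base[1:40, ],
                         c(seq(1, 8, length.out = 10), rep(8, 30)),
                         space = s)
  dec2 <- stopped(flat, stopping_rule())
  expect_true(dec2$stop)
  expect_equal(dec2$reason, "plateau")

  rising <- record_results(empty_experiment_log(s), base[1:10, ],
                           c(1, 1, 1, 1, 1, 1, 1, 1, 1, 3), space = s)
  dec3 <- stopped(rising, stopping_rule())
  expect_false(dec3$stop)
  expect_equal(dec3$reason, "continue")
})

test_that("the best-so-far trace is the running maximum", {
  s <- ivt_space()
  d <- initialize_design(s, n_init = 4, seed = 9)
  log <- record_results(empty_experiment_log(s), d, c(3, 5, 4, 7), space = s)
  tr <- best_so_far_trace(log)
  expect_equal(tr$best_gL, c(3, 5, 5, 7))
  expect_equal(tr$best_gL[4], max(log$yield_gL))

  const <- record_results(empty_experiment_log(s), d, rep(2, 4), space = s)
  expect_equal(best_so_far_trace(const)$best_gL, rep(2, 4))

  expect_error(best_so_far_trace(empty_experiment_log(s)), "empty")

  # property: non-decreasing for random logs
  for (seed in 1:20) {
    y <- withr::with_seed(seed, runif(30, 0, 12))
    log_r <- record_results(empty_experiment_log(s),
                            initialize_design(s, 30, seed = seed), y,
                            space = s)
    expect_true(all(diff(best_so_far_trace(log_r)$best_gL) >= 0))
  }
})

test_that("the closed loop hits its budget and reproduces bit-for-bit", {
  sim <- sim_params()
  log <- run_closed_loop(sim, budget = 24, batch_size = 4, n_init = 16,
                         seed = 11, noise_sd = 0.5,
                         restarts = fast$restarts, maxit = fast$maxit,
                         pool_size = fast$pool_size, n_local = fast$n_local)
  expect_equal(nrow(log), 24)
  expect_equal(sum(log$source == "lhs"), 16)
  expect_equal(sum(log$source == "bo"), 8)
  expect_equal(nrow(validate_conditions(log[ivt_space()$specs$name])), 0)

  log2 <- run_closed_loop(sim, budget = 24, batch_size = 4, n_init = 16,
                          seed = 11, noise_sd = 0.5,
                          restarts = fast$restarts, maxit = fast$maxit,
                          pool_size = fast$pool_size,
                          n_local = fast$n_local)
  expect_identical(log, log2)
})

test_that("experiment logs round-trip through CSV with the exact header", {
  s <- ivt_space()
  d <- initialize_design(s, n_init = 5, seed = 12)
  log <- record_results(empty_experiment_log(s), d, 1:5,
                        replicate_sd = 0.3, space = s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_experiment_log(log, path, s)

  header <- readLines(path, n = 1)
  expect_equal(header,
               paste0("batch_id,source,cofactor,cofactor_mM,DTT_mM,",
                      "RNaseInh_UmL,NTPs_mM,DNA_nM,PPase_UmL,spermidine_mM,",
                      "T7_UmL,temperature_C,time_min,pH,yield_gL,",
                      "replicate_sd_gL"))
  back <- read_experiment_log(path, s)
  expect_equal(as.data.frame(back), as.data.frame(log), tolerance = 1e-9)
})

test_that("parallel-coordinates export is long, scaled and complete", {
  s <- ivt_space()
  d <- initialize_design(s, n_init = 6, seed = 13)
  log <- record_results(empty_experiment_log(s), d, rep(1, 6), space = s)
  pc <- parallel_coordinates_data(log, s)
  expect_equal(nrow(pc), 6 * 12)
  expect_true(all(pc$position >= 0 & pc$position <= 1))
  expect_equal(levels(pc$parameter), s$specs$name)
})
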