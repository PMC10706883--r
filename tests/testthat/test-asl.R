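test_that("kinetic-model signal is zero without flow and continuous at the breakpoints", {
  const <- asl_constants()
  expect_equal(asl_signal(0, 500, 800, 1800, 100, 1500, const), 0)
  expect_equal(asl_signal(200, 500, 800, 400, 100, 1500, const), 0)
  eps <- 1e-9
  for (tb in c(500, 1300)) {   # att and att + tau
    lo <- asl_signal(200, 500, 800, tb - eps, 100, 1500, const)
    hi <- asl_signal(200, 500, 800, tb + eps, 100, 1500, const)
    expect_lt(abs(hi - lo), 1e-9 * max(1, abs(hi)))
  }
})

test_that("the documented unit audit number is what the model computes", {
  dm <- asl_signal(250, 500, 800, 1800, 100, 1500, asl_constants())
  expect_equal(dm, 2.238555, tolerance = 1e-6)
  # and the delivery integral underlying it
  k <- 1 / 1650 - 1 / 1500
  integral <- (exp(-k * 500) - exp(-k * 1300)) / k
  expect_equal(dm, 2 * 0.95 * (100 / 0.9) * (250 / 6e6) *
                 exp(-1800 / 1500) * integral, tolerance = 1e-12)
})

test_that("signal is linear in perfusion and invariant to joint M0/dM scaling", {
  const <- asl_constants()
  s1 <- asl_signal(100, 500, 800, 1800, 100, 1500, const)
  s3 <- asl_signal(300, 500, 800, 1800, 100, 1500, const)
  expect_equal(s3, 3 * s1, tolerance = 1e-12)
  # quantification: doubling M0 and dM together leaves perfusion unchanged
  q1 <- quantify_perfusion(array(s1, c(1, 1, 1)), 500, array(100, c(1, 1, 1)),
                           1500, array(TRUE, c(1, 1, 1)))
  q2 <- quantify_perfusion(array(2 * s1, c(1, 1, 1)), 500,
                           array(200, c(1, 1, 1)), 1500,
                           array(TRUE, c(1, 1, 1)))
  expect_equal(q1$perfusion[1, 1, 1], q2$perfusion[1, 1, 1], tolerance = 1e-12)
  expect_equal(q1$perfusion[1, 1, 1], 100, tolerance = 1e-9)
})

test_that("pairwise subtraction averages to the difference signal and is order-invariant", {
  ph <- small_phantom(noise_sd = 0)
  ser <- simulate_asl_pairs(ph, noise_sd = 0)
  dm <- compute_delta_m(ser)
  vox <- which(ph$masks$cortex)[1]
  truth <- asl_signal(ph$truth$perfusion[vox], ph$truth$att_ms[vox],
                      ph$truth$tau_ms[vox], 1800, ph$truth$m0[vox],
                      ph$truth$t1_ms[vox])
  expect_equal(dm$maps$pld1800[vox], truth, tolerance = 1e-12)
  # permuting volumes (with their sidecar rows) leaves the average unchanged
  set.seed(2)
  perm <- sample(nrow(ser$params))
  ser_p <- acquisition_series(ser$data[, , , perm, drop = FALSE],
                              ser$params[perm, ], ser$voxel_mm, "asl",
                              m0 = ser$m0)
  dm_p <- compute_delta_m(ser_p)
  expect_equal(dm_p$maps$pld1800, dm$maps$pld1800, tolerance = 1e-12)
  # mismatched pair counts are an error
  bad <- acquisition_series(ser$data[, , , -1, drop = FALSE],
                            ser$params[-1, ], ser$voxel_mm, "asl")
  expect_error(compute_delta_m(bad), "mismatched")
})

test_that("averaging many noisy pairs converges to the true difference (Monte-Carlo)", {
  set.seed(77)
  n_pairs <- 1e4
  c_true <- 2
  s <- c_true + rnorm(n_pairs)
  ns <- rnorm(n_pairs)
  dm <- mean(s - ns)
  se <- sqrt(2 / n_pairs)
  expect_lt(abs(dm - c_true), 3 * se)
})

test_that("multi-PLD inflow estimation recovers perfusion and transit time", {
  f_true <- c(250, 100, 400, 60)
  att_true <- c(500, 700, 350, 1100)
  n <- length(f_true)
  truth <- list(t1_ms = voxel_column(n, 1500), m0 = voxel_column(n, 100),
                adc_mm2_s = voxel_column(n, 2e-3),
                t2star_ms = voxel_column(n, 50),
                perfusion = voxel_column(n, f_true),
                att_ms = voxel_column(n, att_true),
                tau_ms = voxel_column(n, 800))
  ph <- truth_phantom(truth)
  # a PLD ladder spanning the transit-time range: delays longer than the
  # last short PLD are needed to pin down late-arriving boluses
  ser <- simulate_asl_pairs(ph, pld_ms = seq(300, 1800, by = 150),
                            pairs = 1, noise_sd = 0)
  dm <- compute_delta_m(ser)
  est <- estimate_inflow(dm, t1_ms = truth$t1_ms, mask = ph$masks$kidney)
  expect_lt(max(abs(est$perfusion[, 1, 1] / f_true - 1)), 0.01)
  expect_lt(max(abs(est$att_ms[, 1, 1] - att_true)), 25)
  # the clinical five-delay protocol identifies transit times it brackets
  ser5 <- simulate_asl_pairs(ph, noise_sd = 0)
  est5 <- estimate_inflow(compute_delta_m(ser5), t1_ms = truth$t1_ms,
                          mask = ph$masks$kidney)
  short <- att_true <= 900
  expect_lt(max(abs(est5$perfusion[short, 1, 1] / f_true[short] - 1)), 0.01)
  expect_lt(max(abs(est5$att_ms[short, 1, 1] - att_true[short])), 25)
  # closed-loop long-PLD quantification is exact given the true transit time
  q <- quantify_perfusion(dm$maps$pld1800, truth$att_ms, truth$m0,
                          truth$t1_ms, ph$masks$kidney)
  expect_lt(max(abs(q$perfusion[, 1, 1] / f_true - 1)), 1e-6)
})

test_that("all-zero difference data yield zero perfusion with flagged transit time", {
  n <- 3
  truth <- list(t1_ms = voxel_column(n, 1500), m0 = voxel_column(n, 100),
                adc_mm2_s = voxel_column(n, 2e-3),
                t2star_ms = voxel_column(n, 50),
                perfusion = voxel_column(n, 1e-12),
                att_ms = voxel_column(n, 500),
                tau_ms = voxel_column(n, 800))
  ph <- truth_phantom(truth)
  dm <- compute_delta_m(simulate_asl_pairs(ph, noise_sd = 0))
  dm$maps <- lapply(dm$maps, function(m) m * 0)   # exactly zero
  est <- estimate_inflow(dm, m0 = truth$m0, t1_ms = truth$t1_ms,
                         mask = ph$masks$kidney)
  expect_true(all(est$perfusion[, 1, 1] == 0))
  expect_true(all(is.na(est$att_ms[, 1, 1])))
  expect_true(all(est$status[, 1, 1] == 1L))
})

test_that("estimated perfusion stays non-negative under noise", {
  set.seed(14)
  n <- 200
  truth <- list(t1_ms = voxel_column(n, 1500), m0 = voxel_column(n, 100),
                adc_mm2_s = voxel_column(n, 2e-3),
                t2star_ms = voxel_column(n, 50),
                perfusion = voxel_column(n, runif(n, 1, 60)),
                att_ms = voxel_column(n, runif(n, 300, 900)),
                tau_ms = voxel_column(n, 800))
  ph <- truth_phantom(truth, noise_sd = 0.02)
  dm <- compute_delta_m(simulate_asl_pairs(ph, seed = 5))
  est <- estimate_inflow(dm, t1_ms = truth$t1_ms, mask = ph$masks$kidney)
  expect_true(all(est$perfusion[, 1, 1] >= 0))
})
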