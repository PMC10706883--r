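test_that("phantom construction is deterministic and respects the spec", {
  spec <- phantom_spec(grid = c(24, 24, 8), seed = 11)
  p1 <- make_phantom(spec)
  p2 <- make_phantom(spec)
  expect_identical(p1$masks$cortex, p2$masks$cortex)
  expect_identical(p1$truth, p2$truth)
  # masks are disjoint and nested in the kidney
  expect_false(any(p1$masks$cortex & p1$masks$medulla))
  expect_true(all(p1$masks$kidney[p1$masks$cortex | p1$masks$medulla]))
  expect_error(make_phantom(phantom_spec(grid = c(6, 24, 8))), "degenerate")
})

test_that("zero intra-tissue dispersion reproduces the truth table exactly", {
  sdz <- default_tissue_sd() * 0
  ph <- make_phantom(phantom_spec(grid = c(24, 24, 8), tissue_sd = sdz))
  expect_true(all(ph$truth$t1_ms[ph$masks$cortex] == 1500))
  expect_true(all(ph$truth$t1_ms[ph$masks$medulla] == 1900))
  expect_true(all(ph$truth$t1_ms[!ph$masks$kidney] == 0))
})

test_that("phantom kidney volume matches the analytic ellipsoid volume", {
  ph <- small_phantom(grid = c(40, 40, 12))
  geo <- renalmri:::phantom_geometry(c(40, 40, 12), 0.6)
  analytic_vox <- 2 * 4 / 3 * pi * prod(geo$left$semi)
  expect_lt(abs(sum(ph$masks$kidney) / analytic_vox - 1), 0.03)
  # and TKV in mL is just count x voxel volume
  tkv <- total_kidney_volume(ph$masks)
  expect_equal(tkv$tkv_ml, sum(ph$masks$kidney) * 45 / 1000)
})

test_that("inversion-recovery signal has its null point at T1 ln 2 and full recovery", {
  tt <- default_tissue_truth()
  tt$t1_ms <- c(1000, 1000)
  ph <- make_phantom(phantom_spec(grid = c(24, 24, 8), tissues = tt,
                                  tissue_sd = default_tissue_sd() * 0,
                                  noise_sd = 0))
  vox <- which(ph$masks$cortex)[1]
  s_null <- simulate_ir_series(ph, ti_ms = c(200, 400, 1000 * log(2), 900, 1200),
                               noise_sd = 0)
  expect_lt(s_null$data[, , , 3][vox], 1e-10)
  s_inf <- simulate_ir_series(ph, ti_ms = c(200, 400, 600, 800, 1e6),
                              noise_sd = 0)
  expect_equal(s_inf$data[, , , 5][vox], ph$truth$m0[vox], tolerance = 1e-12)
})

test_that("diffusion signal follows the mono-exponential closed form", {
  tt <- default_tissue_truth()
  tt$adc_mm2_s <- c(2e-3, 2e-3)
  ph <- make_phantom(phantom_spec(grid = c(24, 24, 8), tissues = tt,
                                  tissue_sd = default_tissue_sd() * 0,
                                  noise_sd = 0))
  ser <- simulate_dwi_series(ph, b_values = c(0, 500), n_directions = 3,
                             noise_sd = 0)
  vox <- which(ph$masks$cortex)[5]
  b0 <- ser$data[, , , which(ser$params$b_s_mm2 == 0)]
  b500 <- ser$data[, , , which(ser$params$b_s_mm2 == 500)]
  for (d in 1:3) expect_equal(b0[, , , d][vox], ph$truth$m0[vox])
  expect_equal(b500[, , , 1][vox] / b0[, , , 1][vox], exp(-1),
               tolerance = 1e-12)
})

test_that("multi-echo signal decays as exp(-TE/T2*) and rejects <3 echoes", {
  tt <- default_tissue_truth()
  tt$t2star_ms <- c(50, 50)
  ph <- make_phantom(phantom_spec(grid = c(24, 24, 8), tissues = tt,
                                  tissue_sd = default_tissue_sd() * 0,
                                  noise_sd = 0))
  ser <- simulate_mfe_series(ph, te_ms = c(5, 20, 35), noise_sd = 0)
  vox <- which(ph$masks$medulla)[1]
  expect_equal(ser$data[, , , 1][vox] / ph$truth$m0[vox], exp(-0.1),
               tolerance = 1e-12)
  expect_error(simulate_mfe_series(ph, te_ms = c(5, 8)), "3 echoes")
})

test_that("ASL pairs difference vanishes without perfusion or before arrival", {
  tt <- default_tissue_truth()
  tt$perfusion <- c(1e-12, 1e-12)   # effectively zero flow
  ph <- make_phantom(phantom_spec(grid = c(20, 20, 8), tissues = tt,
                                  tissue_sd = default_tissue_sd() * 0,
                                  noise_sd = 0))
  ser <- simulate_asl_pairs(ph, noise_sd = 0)
  dm <- compute_delta_m(ser)
  for (m in dm$maps) expect_lt(max(abs(m)), 1e-12)
  # bolus not yet arrived: PLD below the transit time gives exactly zero
  expect_equal(asl_signal(250, att_ms = 500, tau_ms = 800, t_ms = 300,
                          m0 = 100, t1_ms = 1500), 0)
})

test_that("Gaussian noise is unbiased around the noiseless signal; Rician is non-negative", {
  set.seed(99)
  draws <- renalmri:::add_noise(rep(10, 1e4), 1, "gaussian")
  expect_lt(abs(mean(draws) / 10 - 1), 0.01)
  ric <- renalmri:::add_noise(rep(0.5, 1e4), 1, "rician")
  expect_true(all(ric >= 0))
  expect_gt(mean(ric), 0.5)   # magnitude bias at low SNR
})

test_that("noisy series are reproducible under a fixed seed", {
  ph <- small_phantom(noise_sd = 0.02)
  a <- simulate_ir_series(ph, seed = 5)
  b <- simulate_ir_series(ph, seed = 5)
  expect_identical(a$data, b$data)
})

test_that("cohort slope distributions map onto progression labels as the rule dictates", {
  base <- list(progressor = c(50, 0), stable = c(50, 0))
  sp6 <- cohort_spec(n_progressor = 4, n_stable = 4,
                     egfr_intercept = base,
                     egfr_slope = list(progressor = c(-6, 0),
                                       stable = c(-6, 0)),
                     creatinine_cv = 0, seed = 1)
  co6 <- simulate_cohort(sp6)
  expect_true(all(co6$subjects$label_realized == "progressor"))
  sp4 <- cohort_spec(n_progressor = 4, n_stable = 4,
                     egfr_intercept = base,
                     egfr_slope = list(progressor = c(-4, 0),
                                       stable = c(-4, 0)),
                     creatinine_cv = 0, seed = 1)
  co4 <- simulate_cohort(sp4)
  expect_true(all(co4$subjects$label_realized == "stable"))
})

test_that("realized mean slope matches the intended distribution (Monte-Carlo)", {
  sp <- cohort_spec(n_progressor = 100, n_stable = 100,
                    egfr_intercept = list(progressor = c(55, 5),
                                          stable = c(55, 5)),
                    egfr_slope = list(progressor = c(-6, 1.5),
                                      stable = c(-6, 1.5)),
                    creatinine_cv = 0, seed = 31)
  co <- simulate_cohort(sp)
  se <- 1.5 / sqrt(200)
  expect_lt(abs(mean(co$subjects$slope_realized) - (-6)), 3 * se)
  # with zero creatinine noise the realized slope equals the generative one
  expect_equal(co$subjects$slope_realized, co$subjects$slope_true,
               tolerance = 1e-8)
  # intended-progressor fraction relabelled by the rule follows the normal model
  frac <- mean(co$subjects$label_realized == "progressor")
  p_theory <- pnorm((-5 - (-6)) / 1.5)
  expect_lt(abs(frac - p_theory), 3 * sqrt(p_theory * (1 - p_theory) / 200))
})
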