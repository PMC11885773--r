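test_that("free diffusion reproduces MSD(t) = 2 D t", {
  D <- 1e4; dt <- 1e-6; t_end <- 2e-3
  cfg <- sim_config(D = D, duration = t_end, dt = dt, sample_rate = 1 / dt,
                    seed = 11, initial = 0)
  proto <- force_protocol("constant", F0 = 0)
  n <- 2000
  finals <- vapply(seq_len(n), function(r) {
    tr <- run_langevin(flat_potential(), proto, cfg,
                       domain = c(-500, 500), replicate = r)
    tr$extension_nm[nrow(tr)]
  }, numeric(1))
  msd <- mean(finals^2)
  expect_equal(msd, 2 * D * t_end, tolerance = 0.05)
})

test_that("harmonic well equilibrates to the equipartition variance", {
  kappa <- 1; kT <- 4.11; D <- 5e4
  cfg <- sim_config(D = D, duration = 2, sample_rate = 2e4, seed = 3,
                    initial = 0)
  tr <- run_langevin(harmonic_potential(kappa, kT),
                     force_protocol("constant", F0 = 0), cfg)
  v <- mean(tr$extension_nm^2)
  expect_equal(v, kT / kappa, tolerance = 0.05)
})

test_that("trajectories are bit-identical for identical seeds and differ across replicates", {
  p <- fig3d_landscape(force = 7)
  cfg <- sim_config(duration = 0.05, sample_rate = 5000, seed = 9)
  proto <- force_protocol("constant", F0 = 7)
  t1 <- run_langevin(p, proto, cfg)
  t2 <- run_langevin(p, proto, cfg)
  expect_identical(t1$extension_nm, t2$extension_nm)
  t3 <- run_langevin(p, proto, cfg, replicate = 2L)
  expect_false(identical(t1$extension_nm, t3$extension_nm))
})

test_that("unstable configurations are rejected before any stepping", {
  p <- fig3d_landscape(force = 7)
  cfg <- sim_config(D = 5e4, duration = 0.1, dt = 1e-4, sample_rate = 100,
                    seed = 1)
  expect_error(run_langevin(p, force_protocol("constant", F0 = 7), cfg),
               "unstable")
})

test_that("ramp and jump protocols shape the force and extension as expected", {
  p <- fig3d_landscape()
  cfg <- sim_config(duration = 2, sample_rate = 1000, seed = 21,
                    initial = "folded")
  ramp <- run_langevin(p, force_protocol("ramp", F0 = 0, rate = 20), cfg)
  expect_true(all(diff(ramp$force_pN) > 0))
  expect_equal(max(ramp$force_pN), 20 * max(ramp$time_s), tolerance = 1e-6)
  # jump to far above coexistence unfolds; the extension steps up once
  cfgj <- sim_config(duration = 0.4, sample_rate = 2000, seed = 22,
                     initial = "folded")
  jump <- run_langevin(p, force_protocol("jump", F0 = 2, F1 = 30,
                                         jump_time = 0.05), cfgj)
  pre <- jump$extension_nm[jump$time_s < 0.05]
  post <- jump$extension_nm[jump$time_s > 0.3]
  expect_lt(median(pre), 3)
  expect_gt(median(post), 12)
})

test_that("a constant-force trace samples the Boltzmann distribution", {
  p <- fig3d_landscape(force = 7)
  cfg <- sim_config(duration = 20, sample_rate = 1e4, seed = 5,
                    initial = "folded")
  tr <- run_langevin(p, force_protocol("constant", F0 = 7), cfg)
  dom <- attr(tr, "provenance")$domain
  ref <- boltzmann_cdf(p, dom[2])
  emp <- ecdf(tr$extension_nm)
  ks <- max(abs(emp(ref$z) - ref$cdf))
  # short run: coarse agreement here; the tight bound is an acceptance check
  expect_lt(ks, 0.06)
})

test_that("measurement emulation adds calibrated noise and smooths polynomials exactly", {
  flatm <- measurement_model(noise_sd = 0, smoother = "none")
  tr <- make_traj(rep(10, 2000))
  expect_identical(emulate_measurement(tr, flatm)$extension_nm,
                   tr$extension_nm)
  noisy <- emulate_measurement(make_traj(rep(10, 1e5)),
                               measurement_model(noise_sd = 1.5,
                                                 smoother = "none"),
                               seed = 2)
  expect_equal(sd(noisy$extension_nm), 1.5, tolerance = 0.03)
  # 4th-order Savitzky-Golay reproduces a quartic exactly away from edges
  x <- seq(-1, 1, length.out = 501)
  quartic <- 3 + x - 2 * x^2 + 0.5 * x^3 + x^4
  sm <- emulate_measurement(make_traj(quartic),
                            measurement_model(noise_sd = 0,
                                              smoother = "savitzky_golay",
                                              sg_order = 4, sg_window = 51))
  core <- 51:451
  expect_equal(sm$extension_nm[core], quartic[core], tolerance = 1e-8)
  expect_error(
    emulate_measurement(make_traj(rep(1, 20)),
                        measurement_model(sg_window = 51)),
    "window")
})

test_that("first-passage sampling obeys the free-diffusion closed form and D scaling", {
  L <- 10
  tt <- first_passage_times(flat_potential(), force = 0,
                            sim_config(D = 1e4, dt = 2e-6, seed = 13),
                            start = 0, absorb = L, n = 300, reflect = 0)
  expect_equal(mean(tt), L^2 / (2 * 1e4),
               tolerance = 2 * sd(tt) / sqrt(300) / (L^2 / (2 * 1e4)))
  t2 <- first_passage_times(flat_potential(), force = 0,
                            sim_config(D = 2e4, dt = 1e-6, seed = 14),
                            start = 0, absorb = L, n = 300, reflect = 0)
  expect_equal(mean(tt) / mean(t2), 2, tolerance = 0.25)
})

test_that("trajectory files round-trip with their metadata", {
  p <- fig3d_landscape(force = 7)
  cfg <- sim_config(duration = 0.02, sample_rate = 5000, seed = 17)
  tr <- run_langevin(p, force_protocol("constant", F0 = 7), cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$extension_nm, tr$extension_nm, tolerance = 1e-8)
  expect_equal(attr(back, "sample_rate"), attr(tr, "sample_rate"),
               tolerance = 1e-6)
  expect_true(any(grepl("seed: 17", attr(back, "metadata"))))
  # malformed file errors name the offending line
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# junk", "time_s,force_pN,extension_nm",
               "0.001,7,1.0", "0.002,7,oops"), bad)
  expect_error(read_trajectory(bad), "line")
})
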