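test_that("Bell rate law: limits and exact log-linearity", {
  expect_equal(bell_rate(0, k0 = 0.01, x_dagger = 2), 0.01)
  expect_equal(bell_rate(c(1, 7, 30), 0.5, 0), rep(0.5, 3))
  f <- seq(0, 20, by = 2)
  lr <- log(bell_rate(f, 0.01, 2, kT = 4.11))
  slopes <- diff(lr) / diff(f)
  expect_equal(slopes, rep(2 / 4.11, length(slopes)), tolerance = 1e-12)
})

test_that("DHS rate law: Bell recovery at nu = 1, limits, and domain guard", {
  set.seed(5)
  for (i in 1:20) {
    k0 <- 10^runif(1, -4, 1); x <- runif(1, 0.2, 4)
    dG <- runif(1, 30, 120); f <- runif(5, 0, 10)
    expect_equal(dhs_rate(f, k0, x, dG, nu = 1), bell_rate(f, k0, x),
                 tolerance = 1e-14)
    expect_equal(dhs_rate(0, k0, x, dG, nu = 2/3), k0)
    expect_equal(dhs_rate(0, k0, x, dG, nu = 1/2), k0)
  }
  # dG -> infinity converges pointwise to Bell
  expect_equal(dhs_rate(10, 0.01, 2, 1e7, nu = 2/3),
               bell_rate(10, 0.01, 2), tolerance = 1e-4)
  expect_error(dhs_rate(100, 0.01, 2, 50, nu = 2/3), "critical force")
})

test_that("refolding rate law: limits, monotonicity, numerical stability", {
  fjc <- fjc_model(lK = 0.8, dLC = 16.5, kT = 4.11)
  expect_equal(refold_rate(0, 5, fjc), 5)
  tiny <- fjc_model(lK = 0.8, dLC = 1e-9, kT = 4.11)
  expect_equal(refold_rate(c(2, 8, 14), 5, tiny), rep(5, 3),
               tolerance = 1e-8)
  f <- seq(0.1, 60, length.out = 300)
  r <- refold_rate(f, 5, fjc)
  expect_true(all(diff(r) < 0))
  expect_true(all(is.finite(log(r))))  # stable far into the large-u regime
  expect_error(refold_rate(-1, 5, fjc), "force")
})

test_that("the refolding law equals the first-passage integral of the FJC extension", {
  fjc <- fjc_model(lK = 0.8, dLC = 16.5, kT = 4.11)
  k0 <- 9.1
  for (f in c(0.5, 2, 5, 10, 15)) {
    int <- integrate(function(x) fjc_extension(x, fjc), 0, f,
                     rel.tol = 1e-10)$value
    expect_equal(refold_rate(f, k0, fjc), k0 * exp(-int / fjc$kT),
                 tolerance = 1e-6)
  }
})

test_that("rate fitting recovers noiseless synthetic parameters", {
  f <- seq(4, 24, by = 2)
  kT <- 4.11
  # Bell: a linear problem, recovered essentially exactly
  rtb <- rate_table(f, r_fold_per_s = NA, r_unfold_per_s =
                      bell_rate(f, 0.01, 2, kT))
  fb <- fit_rates(rtb, "bell", "unfold", range(f), kT = kT)
  expect_equal(unname(fb$estimates["k0"]), 0.01, tolerance = 1e-8)
  expect_equal(unname(fb$estimates["x_dagger"]), 2, tolerance = 1e-8)
  # DHS
  rtd <- rate_table(f, NA, dhs_rate(f, 0.02, 2.5, 60, nu = 2/3, kT))
  fd <- fit_rates(rtd, "dhs", "unfold", range(f), kT = kT)
  expect_true(fd$converged)
  expect_equal(unname(fd$estimates["x_dagger"]), 2.5, tolerance = 1e-5)
  expect_equal(unname(fd$estimates["dG0_dagger"]), 60, tolerance = 1e-4)
  # FJC refolding, all parameters free
  ff <- seq(1, 10, by = 1.5)
  fjc <- fjc_model(lK = 0.8, dLC = 16.5, kT = kT)
  rtr <- rate_table(ff, refold_rate(ff, 9.1, fjc), NA)
  fr <- fit_rates(rtr, "refold", "fold", range(ff), kT = kT)
  expect_equal(unname(fr$estimates["dLC"]), 16.5, tolerance = 1e-4)
  expect_equal(unname(fr$estimates["lK"]), 0.8, tolerance = 1e-4)
  # freezing the polymer leaves the one-parameter form
  fr1 <- fit_rates(rtr, "refold", "fold", range(ff),
                   frozen = list(dLC = 16.5, lK = 0.8), kT = kT)
  expect_equal(unname(fr1$estimates["k0"]), 9.1, tolerance = 1e-6)
  expect_setequal(fr1$frozen, c("dLC", "lK"))
})

test_that("fit window must contain enough rows", {
  f <- c(5, 6)
  rtd <- rate_table(f, NA, bell_rate(f, 0.01, 2))
  expect_error(fit_rates(rtd, "dhs", "unfold", range(f)), "rows")
})

test_that("ramp rupture-force density normalises and peaks at the closed-form mode", {
  set.seed(12)
  for (i in 1:5) {
    k0 <- 10^runif(1, -4, -1); x <- runif(1, 0.2, 2); a <- 10^runif(1, -1, 1)
    total <- integrate(function(f) ramp_pdf(f, k0, x, a), 0, Inf,
                       rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
    fstar <- ramp_mode(k0, x, a)
    if (fstar > 0) {
      grid <- seq(max(fstar - 5, 0.01), fstar + 5, length.out = 4001)
      expect_equal(grid[which.max(ramp_pdf(grid, k0, x, a))], fstar,
                   tolerance = 0.01)
    }
  }
  # generic survival route agrees with the analytic Bell form
  f <- seq(0.5, 30, length.out = 20)
  expect_equal(ramp_pdf(f, 3.3e-3, 0.22, 1,
                        rate_fun = function(x) bell_rate(x, 3.3e-3, 0.22)),
               ramp_pdf(f, 3.3e-3, 0.22, 1), tolerance = 1e-6)
})

test_that("thinning sampler and ramp distribution agree; faster ramps rupture higher", {
  s1 <- sample_rupture_forces(2000, k0 = 3.3e-3, x_dagger = 0.22, a = 1,
                              seed = 4)
  ks <- max(abs(ecdf(s1)(s1) - ramp_cdf(s1, 3.3e-3, 0.22, 1)))
  expect_lt(ks, 0.04)
  s2 <- sample_rupture_forces(2000, k0 = 3.3e-3, x_dagger = 0.22, a = 2,
                              seed = 5)
  expect_gt(mean(s2), mean(s1))
})

test_that("maximum-likelihood ramp fitting recovers its parameters", {
  f <- sample_rupture_forces(5000, k0 = 3.3e-3, x_dagger = 0.22, a = 1,
                             seed = 7)
  fit <- fit_ramp(f, a = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["k0"]), 3.3e-3, tolerance = 0.10)
  expect_equal(unname(fit$estimates["x_dagger"]), 0.22, tolerance = 0.10)
  bad <- fit_ramp(rep(12, 50), a = 1)
  expect_false(bad$converged)
})

test_that("MFPT double integral matches closed forms", {
  D <- 1e4; L <- 8; kT <- 4.11
  expect_equal(mfpt(function(z) rep(0, length(z)), D, 0, L, 0, kT = kT),
               L^2 / (2 * D), tolerance = 1e-6)
  # linear potential U = c z: T = (kT/(c D)) ((kT/c)(e^(cL/kT) - 1) - L)
  cc <- 1.3
  expect_equal(mfpt(function(z) cc * z, D, 0, L, 0, kT = kT),
               (kT / (cc * D)) * ((kT / cc) * (exp(cc * L / kT) - 1) - L),
               tolerance = 1e-6)
  expect_error(mfpt(function(z) rep(0, length(z)), D, 5, 1, 0, kT = kT),
               "reflect")
})

test_that("fit results serialise as structured text", {
  f <- seq(4, 14, by = 2)
  rtb <- rate_table(f, NA, bell_rate(f, 0.01, 2))
  fit <- fit_rates(rtb, "bell", "unfold", range(f))
  out <- withr::local_tempfile(fileext = ".txt")
  write_fit_result(fit, out)
  txt <- readLines(out)
  expect_true(any(grepl("model: bell", txt)))
  expect_true(any(grepl("^x_dagger,", txt)))
})
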