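test_that("unfolded free energy matches its hand evaluation and derivative", {
  poly <- wlc_model(lP = 0.58, dLC = 19, kT = 4.11)
  # z = 0: bracket reduces to dLC/4, i.e. (kT/lP) * 19/4
  expect_equal(unfolded_free_energy(0, poly), (4.11 / 0.58) * 4.75,
               tolerance = 1e-12)
  # the z-derivative of the F = 0 part is the WLC force law
  z <- seq(0.5, 17, length.out = 50)
  h <- 1e-6
  num <- (unfolded_free_energy(z + h, poly) -
          unfolded_free_energy(z - h, poly)) / (2 * h)
  expect_equal(num, wlc_force(z, poly), tolerance = 1e-6)
  # force tilt is exactly linear
  expect_equal(unfolded_free_energy(z, poly, force = 7) -
               unfolded_free_energy(z, poly, force = 0), -7 * z,
               tolerance = 1e-12)
  expect_error(unfolded_free_energy(19, poly), "dLC")
})

test_that("total potential is the sum of its printed terms", {
  p <- fig3d_landscape()
  poly <- p$polymer
  # at z = z0 = 2: Morse term 50 (1 - e^-2), Gaussian term exactly G
  expect_equal(total_potential(2, p),
               50 * (1 - exp(-2)) + 10 + unfolded_free_energy(2, poly),
               tolerance = 1e-12)
  # at z = 0: Morse 0, Gaussian 10 e^-4
  expect_equal(total_potential(0, p),
               10 * exp(-4) + unfolded_free_energy(0, poly),
               tolerance = 1e-12)
  # additivity over a grid
  z <- seq(0, 18, length.out = 100)
  morse <- 50 * (1 - exp(-z))
  gauss <- 10 * exp(-(z - 2)^2)
  expect_equal(total_potential(z, p),
               morse + gauss + unfolded_free_energy(z, poly, p$force),
               tolerance = 1e-12)
})

test_that("analytic gradient matches numerical differentiation", {
  for (sq in c(FALSE, TRUE)) {
    p <- fig3d_landscape(force = 6, morse_squared = sq)
    z <- seq(0.1, 17, length.out = 60)
    h <- 1e-6
    num <- (total_potential(z + h, p) - total_potential(z - h, p)) / (2 * h)
    expect_equal(potential_gradient(z, p), num, tolerance = 1e-5)
  }
})

test_that("extrema search agrees with a dense brute-force scan", {
  p <- fig3d_landscape()
  ex <- find_extrema(p)
  # brute force over 1e6 points
  z <- seq(0, 6, length.out = 1e6)
  u <- total_potential(z, p)
  d <- diff(u)
  imax <- which(d[-1] < 0 & d[-length(d)] > 0)[1] + 1
  expect_equal(unname(ex$barrier["position"]), z[imax], tolerance = 1e-3)
  expect_equal(unname(ex$folded_min["position"]), 0)
  expect_equal(unname(ex$dG_unfold), u[imax] - u[1], tolerance = 1e-4)
  # positions ordered when all present
  expect_lt(ex$folded_min["position"], ex$barrier["position"])
  expect_lt(ex$barrier["position"], ex$unfolded_min["position"])
})

test_that("extrema search matches brute force on random parameter draws", {
  set.seed(7)
  for (i in 1:5) {
    p <- landscape_params(U0 = runif(1, 30, 80), a = runif(1, 0.5, 2),
                          G = runif(1, 5, 25), z0 = runif(1, 1.5, 3),
                          s = runif(1, 0.5, 2),
                          polymer = wlc_model(lP = 0.58, dLC = 19),
                          force = runif(1, 0, 12))
    ex <- find_extrema(p)
    z <- seq(0, 18, length.out = 1e6)
    u <- total_potential(z, p)
    d <- diff(u)
    imax <- which(d[-1] < 0 & d[-length(d)] > 0) + 1
    if (!is.null(ex$barrier) && length(imax)) {
      expect_equal(unname(ex$barrier["position"]), z[imax[1]],
                   tolerance = 1e-3)
    } else {
      expect_true(is.null(ex$barrier) == (length(imax) == 0))
    }
  }
})

test_that("landscape tilts with force: barrier shrinks, unfolded minimum advances", {
  forces <- seq(0, 20, by = 2)
  dg <- numeric(length(forces)); zu <- numeric(length(forces))
  for (i in seq_along(forces)) {
    ex <- find_extrema(fig3d_landscape(force = forces[i]))
    dg[i] <- ex$dG_unfold
    zu[i] <- if (!is.null(ex$unfolded_min)) ex$unfolded_min["position"]
             else NA
  }
  expect_true(all(diff(dg) <= 1e-8))
  zs <- zu[!is.na(zu)]
  expect_true(all(diff(zs) >= -1e-8))
  # at 10 pN the unfolded minimum sits on the WLC branch
  ex10 <- find_extrema(fig3d_landscape(force = 10))
  expect_equal(unname(ex10$unfolded_min["position"]),
               wlc_extension(10, wlc_model(lP = 0.58, dLC = 19)),
               tolerance = 0.2)
})

test_that("custom potentials work: tilted quadratic has its minimum at F/kappa", {
  kappa <- 2; f <- 5
  ex <- find_extrema(function(z) 0.5 * kappa * z^2 - f * z,
                     domain = c(0, 20))
  expect_equal(unname(ex$folded_min["position"]), f / kappa,
               tolerance = 1e-5)
})

test_that("a monotonic landscape reports absent extrema rather than failing", {
  p <- landscape_params(U0 = 50, a = 1, G = 0, z0 = 2, s = 1,
                        polymer = wlc_model(lP = 0.58, dLC = 19))
  ex <- find_extrema(p)
  expect_null(ex$barrier)
  expect_true(is.na(ex$dG_fold))
  expect_error(kramers_rate(p, D = 1e5), "barrier")
})

test_that("Kramers rate scales linearly in D, decays with barrier height, and tracks the MFPT", {
  p <- fig3d_landscape(force = 10)
  r1 <- kramers_rate(p, D = 1e5)
  expect_equal(kramers_rate(p, D = 2e5) / r1, 2, tolerance = 1e-12)
  pG <- p; pG$G <- 20
  expect_lt(kramers_rate(pG, D = 1e5), r1)
  # high barrier: Kramers vs exact double-integral MFPT within 25%, in
  # the folding direction, whose unfolded well is interior and smooth (the
  # wall-pinned folded minimum violates the Gaussian-well prefactor
  # assumption, so the unfolding direction is not expected to match)
  ph <- fig3d_landscape(force = 6)
  ph$G <- 40   # raises the folding barrier to ~12 kT
  exh <- find_extrema(ph)
  expect_gt(exh$dG_fold / 4.11, 10)
  rk <- kramers_rate(ph, D = 1e5, "fold")
  rm <- 1 / mfpt(ph, 1e5, exh$unfolded_min["position"],
                 exh$folded_min["position"] + 0.02, reflect = 14)
  expect_equal(rk / rm, 1, tolerance = 0.25)
})

test_that("landscape config and table round-trip through text files", {
  cfgfile <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# test landscape", "U0 = 50", "a = 1", "G = 10",
               "z0 = 2", "s = 1", "lP = 0.58", "dLC = 19", "kT = 4.11",
               "force = 4"), cfgfile)
  p <- read_landscape_config(cfgfile)
  expect_equal(p$U0, 50)
  expect_equal(p$force, 4)
  expect_equal(p$polymer$dLC, 19)
  out <- withr::local_tempfile(fileext = ".csv")
  export_landscape(p, out, n = 50)
  tab <- read.csv(out)
  expect_named(tab, c("z_nm", "U_pNnm"))
  expect_equal(tab$U_pNnm, total_potential(tab$z_nm, p), tolerance = 1e-6)
})
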