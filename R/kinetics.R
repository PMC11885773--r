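#' Bell force-dependent escape rate
#'
#' `r(F) = k0 * exp(F * x_dagger / kT)`: exponential force dependence from a
#' barrier a fixed distance `x_dagger` along the pulling coordinate.
#' `x_dagger` is positive for unfolding; negative values are allowed so the
#' model can also be fitted to refolding branches (where the resulting
#' parameters are hard to interpret physically).
#'
#' @param force Force, pN; vectorised.
#' @param k0 Zero-force rate, 1/s (> 0).
#' @param x_dagger Transition-state distance, nm.
#' @param kT Thermal energy, pN.nm.
#' @return Rate in 1/s.
#' @export
bell_rate <- function(force, k0, x_dagger, kT = default_kT()) {
  stopifnot(k0 > 0, kT > 0)
  k0 * exp(force * x_dagger / kT)
}

#' Dudko-Hummer-Szabo escape rate
#'
#' Rate over an explicit barrier shape:
#' `k0 * (1 - nu F x/dG)^(1/nu - 1) * exp((dG/kT) * (1 - (1 - nu F x/dG)^(1/nu)))`
#' with shape parameter `nu` (1/2 quadratic, 2/3 linear-cubic, 1 recovers
#' the Bell model). Valid while `1 - nu F x / dG > 0`; beyond the critical
#' force `dG/(nu x)` the model is undefined.
#'
#' @param force Force, pN; vectorised.
#' @param k0 Zero-force rate, 1/s.
#' @param x_dagger Transition-state distance, nm.
#' @param dG0_dagger Zero-force barrier height, pN.nm (> 0).
#' @param nu Shape parameter, in (0, 1]; default 2/3 (linear-cubic barrier,
#'   a good approximation to most analytic escape barriers).
#' @param kT Thermal energy, pN.nm.
#' @return Rate in 1/s.
#' @export
dhs_rate <- function(force, k0, x_dagger, dG0_dagger, nu = 2/3,
                     kT = default_kT()) {
  stopifnot(k0 > 0, dG0_dagger > 0, nu > 0, nu <= 1, kT > 0)
  # at nu = 1 the barrier factor cancels identically and the Bell model is
  # recovered for all forces, with no domain restriction
  if (nu == 1) return(bell_rate(force, k0, x_dagger, kT))
  q <- 1 - nu * force * x_dagger / dG0_dagger
  if (any(q <= 0))
    stop(sprintf(
      "force beyond DHS domain: critical force is %.4g pN",
      dG0_dagger / (nu * x_dagger)), call. = FALSE)
  k0 * q^(1 / nu - 1) * exp((dG0_dagger / kT) * (1 - q^(1 / nu)))
}

# log(sinh(u)) - log(u), stable for large u via u - log(2u) + log1p(-e^(-2u))
log_sinh_ratio <- function(u) {
  out <- numeric(length(u))
  small <- u < 1e-4
  out[small] <- u[small]^2 / 6          # series limit
  ub <- u[!small]
  out[!small] <- ifelse(ub < 20,
                        log(sinh(ub)) - log(ub),
                        ub - log(2 * ub) + log1p(-exp(-2 * ub)))
  out
}

#' First-passage FJC refolding rate
#'
#' Refolding rate of a force-stretched chain against the entropic free
#' energy of its unfolded state, modelled as a freely-jointed chain:
#' `r_F(F) = k0 * exp(-(dLC/lK) * (log(sinh(u)) - log(u)))`, `u = F lK/kT`.
#' Equals `k0` at zero force and decreases strictly with force; the
#' exponent is the FJC extension integrated over force (the first-passage
#' construction), so `dLC` and `lK` act as an effective energy barrier.
#'
#' @param force Force, pN (>= 0); vectorised.
#' @param k0 Zero-force folding rate, 1/s.
#' @param fjc An [fjc_model()].
#' @return Rate in 1/s.
#' @export
refold_rate <- function(force, k0, fjc) {
  stopifnot(k0 > 0, inherits(fjc, "fjc_model"))
  if (any(force < 0)) stop("force must be non-negative", call. = FALSE)
  u <- force * fjc$lK / fjc$kT
  k0 * exp(-(fjc$dLC / fjc$lK) * log_sinh_ratio(u))
}

new_fit_result <- function(model, which, estimates, se, frozen,
                           force_window, residuals, converged, n,
                           message = NULL) {
  structure(list(model = model, which = which,
                 estimates = estimates, se = se, frozen = frozen,
                 force_window = force_window, residuals = residuals,
                 converged = converged, n = n, message = message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s model (%s), %s\n", x$model, x$which,
              if (x$converged) "converged" else
                paste("FAILED:", x$message %||% "did not converge")))
  est <- data.frame(estimate = x$estimates,
                    sigma = x$se[names(x$estimates)],
                    frozen = names(x$estimates) %in% x$frozen)
  print(est)
  if (!is.null(x$residuals))
    cat(sprintf("  n = %d, residual SD (log rate) = %.4g\n",
                x$n, stats::sd(x$residuals)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a force-dependent rate law to a rate table
#'
#' Weighted least squares on log rate, with weights from event counts
#' (`sigma_logr ~ 1/sqrt(N)`); equal weights when counts are absent.
#' The force window is an explicit argument, never a silent default.
#'
#' @param rt A [rate_table()].
#' @param model `"bell"`, `"dhs"` or `"refold"`.
#' @param which Which branch to fit: `"unfold"` or `"fold"`.
#' @param force_window Length-2 numeric; only rows with force inside the
#'   closed window enter the fit.
#' @param frozen Named list of parameters to hold fixed. For `"refold"`,
#'   freezing both `dLC` and `lK` leaves `k0` as the single free parameter
#'   (the model's natural use when the polymer is independently known).
#' @param nu DHS shape parameter (frozen, not fitted).
#' @param kT Thermal energy, pN.nm.
#' @param start Optional named list of starting values.
#' @return A `fit_result` with estimates, 1-sigma uncertainties from the
#'   Jacobian, and log-rate residuals. Non-convergence gives a `fit_result`
#'   with `converged = FALSE` carrying the last iterate (never a silent
#'   fallback).
#' @export
fit_rates <- function(rt, model = c("bell", "dhs", "refold"),
                      which = c("unfold", "fold"),
                      force_window, frozen = list(), nu = 2/3,
                      kT = default_kT(), start = NULL) {
  model <- match.arg(model); which <- match.arg(which)
  stopifnot(inherits(rt, "rate_table"), length(force_window) == 2)
  rcol <- if (which == "unfold") "r_unfold_per_s" else "r_fold_per_s"
  ncol_ <- if (which == "unfold") "n_unfold" else "n_fold"
  d <- rt[rt$force_pN >= force_window[1] & rt$force_pN <= force_window[2] &
            is.finite(rt[[rcol]]) & rt[[rcol]] > 0, , drop = FALSE]
  w <- d[[ncol_]]
  # event counts give the sampling variance directly (var log r ~ 1/N), so
  # parameter uncertainties then need no residual-variance rescaling
  known_var <- !all(is.na(w))
  if (!known_var) w <- rep(1, nrow(d))
  f <- d$force_pN; lr <- log(d[[rcol]])
  nfree <- switch(model, bell = 2L, dhs = 3L, refold = 3L) -
    length(frozen)
  if (nrow(d) < nfree + 1)
    stop("need at least (free parameters + 1) rows in the force window",
         call. = FALSE)

  if (model == "bell" && is.null(frozen$k0) && is.null(frozen$x_dagger)) {
    fit <- stats::lm(lr ~ f, weights = w)
    co <- stats::coef(fit)
    se <- if (known_var) {
      X <- cbind(1, f) * sqrt(w)
      sqrt(diag(solve(crossprod(X))))
    } else {
      # vcov warns on exactly-interpolating data; zero variances are fine
      sqrt(diag(suppressWarnings(stats::vcov(fit))))
    }
    est <- c(k0 = unname(exp(co[1])), x_dagger = unname(co[2] * kT))
    ses <- c(k0 = unname(exp(co[1]) * se[1]), x_dagger = unname(se[2] * kT))
    return(new_fit_result("bell", which, est, ses, character(0),
                          force_window, stats::residuals(fit), TRUE, nrow(d)))
  }

  # nonlinear models: Levenberg-Marquardt on log rate
  pred <- switch(model,
    bell = function(th) th[["lk0"]] + f * th[["x_dagger"]] / kT,
    dhs = function(th) {
      q <- 1 - nu * f * th[["x_dagger"]] / th[["dG0_dagger"]]
      q <- pmax(q, 1e-10)
      th[["lk0"]] + (1 / nu - 1) * log(q) +
        (th[["dG0_dagger"]] / kT) * (1 - q^(1 / nu))
    },
    refold = function(th) {
      u <- f * th[["lK"]] / kT
      th[["lk0"]] - (th[["dLC"]] / th[["lK"]]) * log_sinh_ratio(u)
    })
  full_start <- switch(model,
    bell = list(lk0 = mean(lr), x_dagger = 1),
    dhs = {
      b <- stats::coef(stats::lm(lr ~ f, weights = w))
      list(lk0 = unname(b[1]), x_dagger = unname(max(b[2] * kT, 0.2)),
           dG0_dagger = 12 * kT)
    },
    refold = list(lk0 = max(lr), dLC = 16, lK = 0.8))
  if (!is.null(start)) full_start[names(start)] <- start
  frozen_vals <- lapply(frozen, identity)
  if ("k0" %in% names(frozen_vals)) {
    frozen_vals$lk0 <- log(frozen_vals$k0); frozen_vals$k0 <- NULL
  }
  free_names <- setdiff(names(full_start), names(frozen_vals))
  th0 <- unlist(full_start[free_names])
  resid_fn <- function(par) {
    th <- c(as.list(par), frozen_vals)
    sqrt(w) * (lr - pred(th))
  }
  out <- try(minpack.lm::nls.lm(
    par = th0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(out, "try-error"))
    return(new_fit_result(model, which, unlist(full_start), NULL,
                          names(frozen_vals), force_window, NULL, FALSE,
                          nrow(d), message = as.character(out)))
  par <- out$par
  dof <- max(nrow(d) - length(par), 1)
  s2 <- if (known_var) 1 else sum(out$fvec^2) / dof
  cov <- try(s2 * solve(out$hessian), silent = TRUE)
  se_par <- if (inherits(cov, "try-error")) rep(NA_real_, length(par))
            else sqrt(pmax(diag(cov), 0))
  names(se_par) <- names(par)
  th <- c(as.list(par), frozen_vals)
  to_nat <- function(th, se) {
    est <- c(); ses <- c()
    for (nm in names(th)) {
      if (nm == "lk0") {
        est["k0"] <- exp(th[[nm]])
        ses["k0"] <- if (!is.na(se[nm] %||% NA)) exp(th[[nm]]) * se[[nm]] else NA
      } else {
        est[nm] <- th[[nm]]
        ses[nm] <- se[nm] %||% NA
      }
    }
    list(est = est, se = ses)
  }
  se_all <- se_par
  nat <- to_nat(th, se_all)
  conv <- out$info %in% 1:4
  new_fit_result(model, which, nat$est, nat$se,
                 sub("^lk0$", "k0", names(frozen_vals)), force_window,
                 out$fvec / sqrt(w), conv, nrow(d),
                 message = if (!conv) out$message)
}

#' Rupture-force density under a linear force ramp
#'
#' Survival-function construction
#' `p(F) = (r(F)/a) * exp(-(1/a) * integral_0^F r(f) df)`. For the Bell
#' rate law the integral is analytic:
#' `p(F) = (k0/a) e^(F x/kT) exp(-(k0 kT/(a x)) (e^(F x/kT) - 1))`.
#' The density integrates to at most 1 on `[0, Inf)`; any deficit is the
#' probability of surviving the ramp.
#'
#' @param force Force, pN; vectorised.
#' @param k0 Zero-force rate, 1/s.
#' @param x_dagger Transition-state distance, nm (> 0 for a proper
#'   distribution).
#' @param a Loading rate, pN/s (> 0).
#' @param kT Thermal energy, pN.nm.
#' @param rate_fun Optional alternative rate law `function(F)`; the
#'   cumulative hazard is then computed by quadrature.
#' @return Density per pN.
#' @export
ramp_pdf <- function(force, k0, x_dagger, a, kT = default_kT(),
                     rate_fun = NULL) {
  stopifnot(a > 0)
  if (is.null(rate_fun)) {
    u <- force * x_dagger / kT
    # assembled in log space: exp(u) overflows long after the density
    # has decayed to zero
    exp(log(k0 / a) + u - (k0 * kT / (a * x_dagger)) * expm1(u))
  } else {
    vapply(force, function(f) {
      H <- stats::integrate(rate_fun, 0, f, rel.tol = 1e-9)$value / a
      rate_fun(f) / a * exp(-H)
    }, numeric(1))
  }
}

#' Ramp rupture-force distribution function
#'
#' `P(F_U <= F)` for the Bell rate law under a linear ramp.
#'
#' @inheritParams ramp_pdf
#' @export
ramp_cdf <- function(force, k0, x_dagger, a, kT = default_kT()) {
  u <- force * x_dagger / kT
  1 - exp(-(k0 * kT / (a * x_dagger)) * (exp(u) - 1))
}

#' Most probable rupture force
#'
#' Mode of the Bell-ramp distribution,
#' `F* = (kT/x) * log(a x / (k0 kT))` (0 when the expression is negative).
#'
#' @inheritParams ramp_pdf
#' @export
ramp_mode <- function(k0, x_dagger, a, kT = default_kT()) {
  max(0, (kT / x_dagger) * log(a * x_dagger / (k0 * kT)))
}

#' Sample rupture forces from a ramp by thinning
#'
#' Draws unfolding forces from a time-inhomogeneous Poisson process with
#' the Bell rate under a linear ramp, by Ogata thinning over 1-pN force
#' windows. This sampling route is independent of [ramp_pdf()] /
#' [ramp_cdf()] and can therefore serve as a cross-check of them.
#'
#' @param n Number of events.
#' @param k0,x_dagger Bell parameters (x_dagger > 0).
#' @param a Loading rate, pN/s.
#' @param kT Thermal energy, pN.nm.
#' @param seed Integer seed.
#' @param f_cap Abort force; events not ruptured by `f_cap` are censored at
#'   `f_cap` (practically none for sensible parameters).
#' @return Numeric vector of rupture forces, pN.
#' @export
sample_rupture_forces <- function(n, k0, x_dagger, a, kT = default_kT(),
                                  seed = 1L, f_cap = 500) {
  stopifnot(x_dagger > 0, a > 0)
  cpp_sample_ramp(as.integer(n), k0, x_dagger, a, kT, as.integer(seed),
                  f_cap)
}

#' Maximum-likelihood fit of ramp rupture forces
#'
#' Fits `(k0, x_dagger)` of the Bell-ramp rupture-force density to observed
#' unfolding forces by direct maximum likelihood; no histogram binning
#' enters the objective (histograms are for display only).
#'
#' @param unfolding_forces Observed rupture forces, pN (>= 10 events).
#' @param a Loading rate, pN/s.
#' @param kT Thermal energy, pN.nm.
#' @return A `fit_result` with estimates and 1-sigma uncertainties from the
#'   observed information matrix.
#' @export
fit_ramp <- function(unfolding_forces, a, kT = default_kT()) {
  f <- unfolding_forces
  stopifnot(length(f) >= 10, a > 0)
  if (stats::sd(f) == 0)
    return(new_fit_result("bell_ramp", "unfold",
                          c(k0 = NA_real_, x_dagger = NA_real_), NULL,
                          character(0), range(f), NULL, FALSE, length(f),
                          message = "degenerate sample: all forces equal"))
  nll <- function(par) {
    k0 <- exp(par[1]); x <- exp(par[2])
    u <- f * x / kT
    -sum(log(k0 / a) + u - (k0 * kT / (a * x)) * (exp(u) - 1))
  }
  # moment-flavoured start: mode and width of the observed distribution
  x0 <- max(kT / max(stats::sd(f), 0.1) * 1.2, 0.05)
  k00 <- a * x0 / kT * exp(-mean(f) * x0 / kT)
  opt <- stats::optim(c(log(k00), log(x0)), nll, method = "BFGS",
                      hessian = TRUE)
  est <- c(k0 = unname(exp(opt$par[1])), x_dagger = unname(exp(opt$par[2])))
  vc <- try(solve(opt$hessian), silent = TRUE)
  se <- if (inherits(vc, "try-error")) c(k0 = NA_real_, x_dagger = NA_real_)
        else c(k0 = est[["k0"]] * sqrt(max(vc[1, 1], 0)),
               x_dagger = est[["x_dagger"]] * sqrt(max(vc[2, 2], 0)))
  new_fit_result("bell_ramp", "unfold", est, se, character(0), range(f),
                 NULL, opt$convergence == 0, length(f),
                 message = if (opt$convergence != 0) "optim did not converge")
}

#' Mean first-passage time by double quadrature
#'
#' Exact overdamped 1-D mean first-passage time
#' `(1/D) * integral_start^absorb dz e^(U/kT) integral_reflect^z dz' e^(-U/kT)`
#' by adaptive quadrature; the brute-force oracle for simulated rates.
#' Either orientation (absorb above or below `start`) is supported with the
#' reflecting boundary on the far side.
#'
#' @param p A [landscape_params()], or a potential function `U(z)` in pN.nm
#'   (then `kT` must be given).
#' @param D Diffusion coefficient, nm^2/s.
#' @param start Starting position, nm.
#' @param absorb Absorbing boundary, nm.
#' @param reflect Reflecting boundary, nm (on the opposite side of `start`
#'   from `absorb`).
#' @param kT Thermal energy for a function potential.
#' @param rel_tol Quadrature relative tolerance.
#' @return Mean first-passage time, s.
#' @export
mfpt <- function(p, D, start, absorb, reflect, kT = NULL,
                 rel_tol = 1e-6) {
  if (inherits(p, "landscape_params")) {
    U <- function(z) total_potential(z, p)
    kT <- p$polymer$kT
  } else if (is.function(p)) {
    if (is.null(kT)) stop("kT required for a function potential",
                          call. = FALSE)
    U <- p
  } else stop("p must be landscape_params or a function", call. = FALSE)
  if (!((reflect <= start && start < absorb) ||
        (absorb < start && start <= reflect)))
    stop("require reflect <= start < absorb (or mirrored)", call. = FALSE)
  Uvals <- U(seq(min(reflect, absorb), max(reflect, absorb), length.out = 200))
  if (any(!is.finite(Uvals)))
    stop("potential not finite on the integration path", call. = FALSE)
  uref <- min(Uvals)  # shift to avoid overflow in exp
  if (absorb > start) {
    inner <- function(z) stats::integrate(function(x) exp(-(U(x) - uref) / kT),
                                          reflect, z,
                                          rel.tol = rel_tol / 10)$value
    f <- Vectorize(function(z) exp((U(z) - uref) / kT) * inner(z))
    stats::integrate(f, start, absorb, rel.tol = rel_tol)$value / D
  } else {
    inner <- function(z) stats::integrate(function(x) exp(-(U(x) - uref) / kT),
                                          z, reflect,
                                          rel.tol = rel_tol / 10)$value
    f <- Vectorize(function(z) exp((U(z) - uref) / kT) * inner(z))
    stats::integrate(f, absorb, start, rel.tol = rel_tol)$value / D
  }
}

#' Serialise a fit result as structured text
#'
#' One `parameter, estimate, sigma, frozen` row per parameter plus header
#' lines naming the model and force window.
#'
#' @param x A `fit_result`.
#' @param path Output file.
#' @export
write_fit_result <- function(x, path) {
  stopifnot(inherits(x, "fit_result"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# model: %s", x$model),
               sprintf("# branch: %s", x$which),
               sprintf("# force_window_pN: %g %g",
                       x$force_window[1], x$force_window[2]),
               sprintf("# converged: %s", x$converged)), con)
  df <- data.frame(parameter = names(x$estimates),
                   estimate = unname(x$estimates),
                   sigma = unname(x$se[names(x$estimates)]),
                   frozen = names(x$estimates) %in% x$frozen)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate a fitted rate law over a force grid
#'
#' @param fit A `fit_result` from [fit_rates()].
#' @param force Force grid, pN.
#' @param nu DHS shape parameter (must match the one used in the fit).
#' @param kT Thermal energy, pN.nm.
#' @return Rate in 1/s.
#' @export
predict_rate <- function(fit, force, nu = 2/3, kT = default_kT()) {
  stopifnot(inherits(fit, "fit_result"))
  e <- fit$estimates
  switch(fit$model,
    bell = bell_rate(force, e[["k0"]], e[["x_dagger"]], kT),
    dhs = dhs_rate(force, e[["k0"]], e[["x_dagger"]], e[["dG0_dagger"]],
                   nu = nu, kT = kT),
    refold = refold_rate(force, e[["k0"]],
                         fjc_model(lK = e[["lK"]], dLC = e[["dLC"]],
                                   kT = kT)),
    stop(sprintf("cannot evaluate model '%s'", fit$model), call. = FALSE))
}

#' Export a fitted rate curve as CSV
#'
#' Columns `force_pN, rate_per_s, model`.
#'
#' @inheritParams predict_rate
#' @param path Output file.
#' @export
export_rate_curve <- function(fit, force, path, nu = 2/3,
                              kT = default_kT()) {
  utils::write.csv(data.frame(force_pN = force,
                              rate_per_s = predict_rate(fit, force, nu, kT),
                              model = fit$model),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
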