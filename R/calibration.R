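#' Equipartition force from lateral bead fluctuations
#'
#' `F = kT * <z> / <dy^2>`: the pulling force on a tethered bead from its
#' mean extension and the variance of its lateral fluctuations
#' (time-domain equipartition; spectral shutter/drag corrections are out of
#' scope).
#'
#' @param mean_extension Mean tether extension `<z>`, nm.
#' @param lateral_variance Lateral fluctuation variance `<dy^2>`, nm^2
#'   (> 0).
#' @param kT Thermal energy, pN.nm.
#' @return Force in pN; vectorised.
#' @export
equipartition_force <- function(mean_extension, lateral_variance,
                                kT = default_kT()) {
  if (any(lateral_variance <= 0))
    stop("lateral variance must be positive", call. = FALSE)
  kT * mean_extension / lateral_variance
}

#' Exponential magnet-position force law
#'
#' Phenomenological permanent-magnet calibration `F(MP) = A * exp(-B * MP)`.
#' The magnet position is treated as a unitless control value, so `A`
#' (pN) and `B` are dataset-specific. An optional double-exponential
#' extension `A exp(-B MP) + A2 exp(-B2 MP)` is available for saturation
#' effects.
#'
#' @param mp Magnet position (control value); vectorised.
#' @param A,B Law parameters (`A` in pN, both > 0).
#' @param A2,B2 Optional second exponential (both `NULL` by default).
#' @return Force in pN.
#' @export
exp_magnet_force <- function(mp, A, B, A2 = NULL, B2 = NULL) {
  stopifnot(A > 0, B > 0)
  out <- A * exp(-B * mp)
  if (!is.null(A2)) {
    stopifnot(!is.null(B2))
    out <- out + A2 * exp(-B2 * mp)
  }
  out
}

#' Tape-head electromagnet force law
#'
#' `F(z, I) = A I^2 atan(g/2/z) / (1 + (z/(g/2))^2) + B I / (1 + (z/(g/2))^2)`
#' for a magnetic tape head with gap `g` at distance `z`. The quadratic
#' term is polarity-independent; the linear term flips sign with the
#' current.
#'
#' @param current Electric current I, A; vectorised.
#' @param A Quadratic coefficient, pN/A^2.
#' @param B Linear coefficient, pN/A.
#' @param z Head-bead distance, um (> 0).
#' @param g Gap width, um (> 0); tape heads have very narrow gaps
#'   (~25 um).
#' @return Force in pN.
#' @export
tapehead_force <- function(current, A, B, z, g) {
  stopifnot(z > 0, g > 0)
  hw <- g / 2
  lorentz <- 1 / (1 + (z / hw)^2)
  A * current^2 * atan(hw / z) * lorentz + B * current * lorentz
}

#' Predicted unfolding step size at a force
#'
#' WLC extension of the released contour length at force `F`; the
#' step-size observable used for instrument calibration. `folded_size` is
#' retained for documentation clarity but is already absorbed into the
#' model's contour-length change (default 0).
#'
#' @param force Force, pN (> 0); vectorised.
#' @param protein A [wlc_model()] of the protein's contour-length change.
#' @param folded_size Folded-state size, nm (default 0; informational).
#' @return Step size in nm.
#' @export
predicted_step <- function(force, protein, folded_size = 0) {
  stopifnot(inherits(protein, "wlc_model"))
  wlc_extension(force, protein)
}

#' Calibration dataset of step sizes vs control value
#'
#' @param control Control values (magnet position or current, matching the
#'   law to be fitted).
#' @param step_nm Observed unfolding step sizes, nm.
#' @param step_se_nm Step-size standard errors, nm (default 1: unweighted).
#' @return A `calibration_dataset` data frame.
#' @export
calibration_dataset <- function(control, step_nm, step_se_nm = 1) {
  stopifnot(length(control) == length(step_nm), all(step_nm > 0),
            all(step_se_nm > 0))
  structure(data.frame(control = control, step_nm = step_nm,
                       step_se_nm = step_se_nm),
            class = c("calibration_dataset", "data.frame"))
}

#' Fit a force law to step-size calibration data
#'
#' Least squares in observed-step space: minimises
#' `sum(((step_obs - predicted_step(law(control; theta))) / se)^2)`,
#' so heteroscedastic step noise propagates correctly (inverting the WLC
#' would amplify noise at high force). Calibration points whose fitted
#' force falls where step sensitivity is low (> ~85% of the contour
#' length) are flagged.
#'
#' @param data A [calibration_dataset()].
#' @param protein A [wlc_model()] for the calibrant protein.
#' @param law `"exp"` (magnet position, [exp_magnet_force()]) or
#'   `"tapehead"` ([tapehead_force()]; requires `z` and `g`).
#' @param z,g Tape-head geometry (um), required for `law = "tapehead"`.
#' @param start Optional named list of starting values (`A`, `B`).
#' @return A `fit_result` with `A`, `B` estimates and uncertainties; the
#'   fitted force law is available through [calibrated_force()].
#' @export
fit_magnet_law <- function(data, protein, law = c("exp", "tapehead"),
                           z = NULL, g = NULL, start = NULL) {
  law <- match.arg(law)
  stopifnot(inherits(data, "calibration_dataset"),
            inherits(protein, "wlc_model"), nrow(data) >= 3)
  if (law == "tapehead") stopifnot(!is.null(z), !is.null(g))
  force_fn <- switch(law,
    exp = function(ctrl, A, B) exp_magnet_force(ctrl, A, B),
    tapehead = function(ctrl, A, B) tapehead_force(ctrl, A, B, z = z, g = g))
  pred <- function(ctrl, A, B) {
    f <- force_fn(ctrl, A, B)
    f <- pmax(f, 1e-6)
    predicted_step(f, protein)
  }
  if (is.null(start)) {
    start <- if (law == "exp") {
      # log-linear starting guess from WLC-inverted forces
      finv <- vapply(data$step_nm, function(sz)
        wlc_force(min(sz, protein$dLC * 0.999), protein), numeric(1))
      co <- stats::coef(stats::lm(log(finv) ~ data$control))
      list(A = unname(exp(co[1])), B = unname(max(-co[2], 1e-3)))
    } else list(A = 50, B = 5)
  }
  resid_fn <- function(par) {
    (data$step_nm - pred(data$control, par[1], par[2])) / data$step_se_nm
  }
  out <- try(minpack.lm::nls.lm(
    par = c(A = start$A, B = start$B), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(out, "try-error"))
    return(new_fit_result(paste0("calibration_", law), "calibration",
                          unlist(start), NULL, character(0),
                          range(data$control), NULL, FALSE, nrow(data),
                          message = as.character(out)))
  dof <- max(nrow(data) - 2, 1)
  # with user-supplied (absolute) step errors the residuals are already on
  # the unit-variance scale; only the unweighted default rescales by the
  # residual variance
  s2 <- if (all(data$step_se_nm == 1)) sum(out$fvec^2) / dof else 1
  vc <- try(s2 * solve(out$hessian), silent = TRUE)
  se <- if (inherits(vc, "try-error")) c(A = NA_real_, B = NA_real_)
        else stats::setNames(sqrt(pmax(diag(vc), 0)), c("A", "B"))
  fitted_force <- force_fn(data$control, out$par[1], out$par[2])
  flagged <- predicted_step(pmax(fitted_force, 1e-6), protein) >
    0.85 * protein$dLC
  res <- new_fit_result(paste0("calibration_", law), "calibration",
                        c(A = unname(out$par[1]), B = unname(out$par[2])),
                        se, character(0), range(data$control),
                        out$fvec, out$info %in% 1:4, nrow(data),
                        message = if (!(out$info %in% 1:4)) out$message)
  res$law <- law; res$geometry <- list(z = z, g = g)
  res$low_sensitivity <- flagged
  res
}

#' Evaluate a fitted calibration law
#'
#' @param fit A `fit_result` from [fit_magnet_law()].
#' @param control Control values.
#' @return Force in pN.
#' @export
calibrated_force <- function(fit, control) {
  stopifnot(inherits(fit, "fit_result"), !is.null(fit$law))
  A <- fit$estimates[["A"]]; B <- fit$estimates[["B"]]
  if (fit$law == "exp") exp_magnet_force(control, A, B)
  else tapehead_force(control, A, B, z = fit$geometry$z, g = fit$geometry$g)
}

#' Export a fitted force law as a control-force table
#'
#' CSV with columns `control, force_pN`, preceded by a commented
#' fitted-parameter block.
#'
#' @param fit A `fit_result` from [fit_magnet_law()].
#' @param control Control-value grid to tabulate.
#' @param path Output file.
#' @export
export_force_law <- function(fit, control, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# law: %s", fit$law),
               sprintf("# A: %.10g (sigma %.4g)", fit$estimates[["A"]],
                       fit$se[["A"]]),
               sprintf("# B: %.10g (sigma %.4g)", fit$estimates[["B"]],
                       fit$se[["B"]])), con)
  utils::write.csv(data.frame(control = control,
                              force_pN = calibrated_force(fit, control)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write calibration datasets as CSV
#'
#' Fixed header `control,step_nm,step_se_nm`.
#'
#' @param x A [calibration_dataset()].
#' @param path File path.
#' @rdname calibration_io
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "calibration_dataset"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("control", "step_nm") %in% names(df)))
    stop("not a calibration dataset: missing columns", call. = FALSE)
  if (is.null(df$step_se_nm)) df$step_se_nm <- 1
  calibration_dataset(df$control, df$step_nm, df$step_se_nm)
}

#' Read a fluctuation-calibration dataset
#'
#' CSV with header `control,mean_z_nm,var_y_nm2` (tether extension and
#' lateral fluctuation variance per control value); returns the table with
#' the equipartition force added as `force_pN`.
#'
#' @param path Input file.
#' @param kT Thermal energy, pN.nm.
#' @return Data frame with columns `control`, `mean_z_nm`, `var_y_nm2`,
#'   `force_pN`.
#' @export
read_fluctuations <- function(path, kT = default_kT()) {
  df <- utils::read.csv(path)
  need <- c("control", "mean_z_nm", "var_y_nm2")
  if (!all(need %in% names(df)))
    stop("not a fluctuation dataset: missing columns", call. = FALSE)
  df$force_pN <- equipartition_force(df$mean_z_nm, df$var_y_nm2, kT)
  df
}
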