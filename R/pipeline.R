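#' Simulate a force-dependent rate table by first-passage sampling
#'
#' For each force on the unfolding grid, samples first-passage times from
#' the folded minimum to the unfolded minimum (reflecting wall at 0) and
#' reports the rate `1/mean(time)`; for each force on the refolding grid,
#' the mirrored passage from the unfolded minimum to the folded minimum.
#' Event streams at different forces use disjoint replicate indices derived
#' from the master seed.
#'
#' @param p A [landscape_params()] (its `force` field is overridden per
#'   grid point).
#' @param cfg A [sim_config()]; `duration` is ignored.
#' @param forces_unfold,forces_refold Force grids, pN (either may be
#'   empty).
#' @param n_events Events per force (>= 100 recommended for ~10% rate
#'   precision).
#' @param absorb_offset Offset from the folded minimum at which a
#'   refolding passage is scored, nm.
#' @param verbose Print progress to stderr.
#' @return A [rate_table()] with per-force rates, event counts and 95%
#'   CIs on the branch sampled at that force.
#' @export
simulate_rate_table <- function(p, cfg, forces_unfold, forces_refold,
                                n_events = 100, absorb_offset = 0.05,
                                verbose = FALSE) {
  stopifnot(inherits(p, "landscape_params"), inherits(cfg, "sim_config"))
  all_forces <- sort(unique(c(forces_unfold, forces_refold)))
  rows <- lapply(seq_along(all_forces), function(i) {
    f <- all_forces[i]
    pf <- p; pf$force <- f
    ex <- find_extrema(pf)
    zf <- if (!is.null(ex$folded_min)) unname(ex$folded_min["position"]) else 0
    zu <- if (!is.null(ex$unfolded_min)) unname(ex$unfolded_min["position"])
          else wlc_extension(max(f, 0.5), p$polymer)
    ru <- nu_ <- ciu <- NA; rf <- nf_ <- NA
    if (f %in% forces_unfold) {
      if (verbose) message(sprintf("unfolding passages at %g pN", f))
      tt <- first_passage_times(pf, f, cfg, start = zf, absorb = zu,
                                n = n_events, reflect = 0,
                                seed_base = 1000L * i)
      ru <- 1 / mean(tt); nu_ <- n_events
      ciu <- ru * c(1 - 1.96 / sqrt(n_events), 1 + 1.96 / sqrt(n_events))
    }
    if (f %in% forces_refold) {
      if (verbose) message(sprintf("refolding passages at %g pN", f))
      tt <- first_passage_times(pf, f, cfg, start = zu,
                                absorb = zf + absorb_offset,
                                n = n_events, seed_base = 1000L * i + 500L)
      rf <- 1 / mean(tt); nf_ <- n_events
    }
    data.frame(force_pN = f, r_fold_per_s = rf, r_unfold_per_s = ru,
               n_fold = nf_, n_unfold = nu_,
               ci_lo = ciu[1], ci_hi = ciu[2])
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("rate_table", "data.frame"))
}

#' Simulated-landscape rate analysis workflow
#'
#' The full constant-force analysis pipeline on a simulated landscape:
#' first-passage rate sampling over unfolding and refolding force grids,
#' Bell and DHS fits to the unfolding branch, the FJC first-passage fit to
#' the refolding branch (contour and Kuhn lengths free by default), folding
#' probabilities and the coexistence force.
#'
#' Default force grids are ~5-25 pN for unfolding and ~2-10 pN for
#' refolding; the Bell fit is restricted to forces at or below 15 pN, where
#' its linear log-rate approximation holds, while the DHS fit uses the full
#' range.
#'
#' @param p A [landscape_params()].
#' @param cfg A [sim_config()].
#' @param forces_unfold,forces_refold Force grids, pN.
#' @param n_events Events per force.
#' @param bell_max_force Upper force bound of the Bell unfolding fit, pN.
#' @param verbose Print progress.
#' @return A list of class `fig3_result`: `rate_table`, `fits` (named list
#'   `bell_unfold`, `dhs_unfold`, `refold`, `bell_refold`, `dhs_refold`),
#'   `pf` (folding-probability table) and `coexistence`.
#' @export
fig3_pipeline <- function(p, cfg,
                          forces_unfold = c(5, 7, 9, 11, 13, 15, 18, 21, 25),
                          forces_refold = c(2, 3.5, 5, 6.5, 8, 10),
                          n_events = 100, bell_max_force = 15,
                          verbose = FALSE) {
  rt <- simulate_rate_table(p, cfg, forces_unfold, forces_refold, n_events,
                            verbose = verbose)
  kT <- p$polymer$kT
  fits <- list(
    bell_unfold = fit_rates(rt, "bell", "unfold",
                            c(min(forces_unfold), bell_max_force), kT = kT),
    dhs_unfold = fit_rates(rt, "dhs", "unfold", range(forces_unfold),
                           kT = kT),
    refold = fit_rates(rt, "refold", "fold", range(forces_refold), kT = kT),
    bell_refold = fit_rates(rt, "bell", "fold", range(forces_refold),
                            kT = kT),
    dhs_refold = tryCatch(
      fit_rates(rt, "dhs", "fold", range(forces_refold), kT = kT,
                start = list(x_dagger = -3, dG0_dagger = 30)),
      error = function(e) NULL))
  both <- is.finite(rt$r_fold_per_s) & is.finite(rt$r_unfold_per_s)
  pf <- NULL
  if (any(both))
    pf <- data.frame(force_pN = rt$force_pN[both],
                     p_fold = folding_probability(rt$r_fold_per_s[both],
                                                  rt$r_unfold_per_s[both]))
  cx <- tryCatch(coexistence_force(rt), error = function(e) NULL)
  structure(list(rate_table = rt, fits = fits, pf = pf, coexistence = cx),
            class = "fig3_result")
}

#' @export
print.fig3_result <- function(x, ...) {
  cat("Simulated-landscape rate analysis\n")
  cat(sprintf("  %d forces, unfolding %s pN, refolding %s pN\n",
              nrow(x$rate_table),
              paste(range(x$rate_table$force_pN[
                is.finite(x$rate_table$r_unfold_per_s)]), collapse = "-"),
              paste(range(x$rate_table$force_pN[
                is.finite(x$rate_table$r_fold_per_s)]), collapse = "-")))
  b <- x$fits$bell_unfold$estimates
  cat(sprintf("  Bell (unfold):   k0 = %.3g /s, x+ = %.3f nm\n",
              b[["k0"]], b[["x_dagger"]]))
  d <- x$fits$dhs_unfold$estimates
  cat(sprintf("  DHS  (unfold):   k0 = %.3g /s, x+ = %.3f nm, dG0+ = %.1f pN.nm\n",
              d[["k0"]], d[["x_dagger"]], d[["dG0_dagger"]]))
  r <- x$fits$refold$estimates
  cat(sprintf("  FJC  (refold):   k0 = %.3g /s, dLC = %.2f nm, lK = %.3f nm\n",
              r[["k0"]], r[["dLC"]], r[["lK"]]))
  if (!is.null(x$coexistence))
    cat(sprintf("  coexistence force F0.5 = %.2f pN\n", x$coexistence$f_half))
  invisible(x)
}

#' Analyse a trajectory into states, dwells, rates and steps
#'
#' The constant-force experimental analysis chain: dual-threshold state
#' assignment, dwell extraction, exponential rate estimates for both
#' states, step sizes at transitions, and the empirical folded fraction.
#'
#' @param traj A `mt_trajectory`.
#' @param low,high Hysteresis thresholds, nm.
#' @param step_window Flanking window for step measurement, s.
#' @return List with `states`, `dwells`, `rates` (list with `fold`,
#'   `unfold`), `steps` (NULL when the trace has no transitions),
#'   `folded_fraction`.
#' @export
analyze_trajectory <- function(traj, low, high, step_window = 0.5) {
  states <- assign_states(traj, low, high)
  dwells <- extract_dwells(states, traj)
  rates <- list(unfold = estimate_rates(dwells, "folded"),
                fold = estimate_rates(dwells, "unfolded"))
  steps <- tryCatch(measure_steps(traj, states, window = step_window),
                    error = function(e) NULL)
  list(states = states, dwells = dwells, rates = rates, steps = steps,
       folded_fraction = folded_fraction(states))
}
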