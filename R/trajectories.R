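#' Two-state assignment by dual-threshold (Schmitt trigger)
#'
#' Labels each sample folded or unfolded with a hysteresis band: the state
#' flips to unfolded only when the extension rises above `high` and back to
#' folded only when it falls below `low`; samples inside the band keep the
#' previous label. The initial label comes from the nearer threshold. The
#' hysteresis makes the labelling robust to the ~1.5 nm measurement noise.
#'
#' @param traj A `mt_trajectory`.
#' @param low,high Thresholds in nm, `low < high`. Sensible defaults are the
#'   midpoint between the two landscape minima +/- 25% of their separation;
#'   see [default_thresholds()].
#' @return An object of class `state_sequence`: integer vector (1 folded,
#'   2 unfolded) with `levels` and `thresholds` attributes.
#' @export
assign_states <- function(traj, low, high) {
  stopifnot(inherits(traj, "mt_trajectory"), is.numeric(low),
            is.numeric(high))
  if (low >= high) stop("thresholds must satisfy low < high", call. = FALSE)
  s <- cpp_schmitt(traj$extension_nm, low, high)
  structure(s, class = "state_sequence",
            levels = c("folded", "unfolded"),
            thresholds = c(low = low, high = high))
}

#' Default hysteresis thresholds from a landscape
#'
#' Midpoint between the folded and unfolded minima at the landscape's
#' force, plus/minus `band` times their separation.
#'
#' @param p A [landscape_params()] whose `force` field is the working force.
#' @param band Half-width of the hysteresis band as a fraction of the
#'   minima separation (default 0.25).
#' @return `c(low, high)` in nm.
#' @export
default_thresholds <- function(p, band = 0.25) {
  ex <- find_extrema(p)
  if (is.null(ex$folded_min) || is.null(ex$unfolded_min))
    stop("landscape is not two-state at this force", call. = FALSE)
  zf <- ex$folded_min["position"]; zu <- ex$unfolded_min["position"]
  mid <- (zf + zu) / 2; half <- band * (zu - zf)
  unname(c(mid - half, mid + half))
}

#' @export
print.state_sequence <- function(x, ...) {
  tab <- table(factor(unclass(x), 1:2, c("folded", "unfolded")))
  cat(sprintf("state_sequence: %d samples (%d folded, %d unfolded), %d transitions\n",
              length(x), tab[1], tab[2], sum(diff(unclass(x)) != 0)))
  invisible(x)
}

#' Extract dwell intervals from a state sequence
#'
#' Residence intervals per state; the first and last intervals are flagged
#' censored (their true start/end was not observed). Durations are measured
#' between threshold-crossing samples and tile the trace exactly.
#'
#' @param states A `state_sequence` from [assign_states()].
#' @param traj The matching `mt_trajectory`.
#' @return A `dwell_table`: data frame with columns `state`, `start_s`,
#'   `duration_s`, `censored`.
#' @export
extract_dwells <- function(states, traj) {
  stopifnot(inherits(states, "state_sequence"),
            inherits(traj, "mt_trajectory"),
            length(states) == nrow(traj))
  s <- as.vector(unclass(states))
  r <- rle(s)
  n <- length(r$lengths)
  ends <- cumsum(r$lengths)
  dt <- 1 / attr(traj, "sample_rate")
  t0 <- traj$time_s[1]
  # interval boundaries at the crossing samples; the trace spans
  # [t0 - dt, last sample] so durations sum to nrow * dt
  bounds <- c(t0 - dt, traj$time_s[ends])
  out <- data.frame(
    state = c("folded", "unfolded")[r$values],
    start_s = bounds[-length(bounds)],
    duration_s = diff(bounds),
    censored = seq_len(n) %in% c(1L, n))
  structure(out, class = c("dwell_table", "data.frame"))
}

#' Exponential rate estimate from dwell times
#'
#' Maximum-likelihood rate for one state's dwells,
#' `r = N_events / sum(durations)`, where censored dwells contribute to the
#' denominator but not the event count (standard survival treatment), with
#' a 95% chi-square confidence interval. With zero events only a one-sided
#' upper bound is reported.
#'
#' @param dwells A `dwell_table`.
#' @param state `"folded"` or `"unfolded"`; the rate of leaving this state.
#' @param conf Confidence level.
#' @return List with `rate` (NA when no events), `n_events`, `total_time`,
#'   `ci` (2-vector).
#' @export
estimate_rates <- function(dwells, state = c("folded", "unfolded"),
                           conf = 0.95) {
  state <- match.arg(state)
  stopifnot(inherits(dwells, "dwell_table"))
  d <- dwells[dwells$state == state, , drop = FALSE]
  if (!nrow(d))
    return(list(rate = NA_real_, n_events = 0L, total_time = 0,
                ci = c(NA_real_, NA_real_)))
  total <- sum(d$duration_s)
  nev <- sum(!d$censored)
  a <- 1 - conf
  if (nev == 0L) {
    return(list(rate = NA_real_, n_events = 0L, total_time = total,
                ci = c(0, stats::qchisq(conf, 2) / (2 * total))))
  }
  list(rate = nev / total, n_events = nev, total_time = total,
       ci = c(stats::qchisq(a / 2, 2 * nev) / (2 * total),
              stats::qchisq(1 - a / 2, 2 * (nev + 1)) / (2 * total)))
}

#' Folding probability from rates
#'
#' `P_F = r_F / (r_F + r_U)`, the equilibrium folded fraction of a
#' two-state system.
#'
#' @param r_fold Folding rate, 1/s.
#' @param r_unfold Unfolding rate, 1/s.
#' @return Probability in `[0, 1]`; vectorised.
#' @export
folding_probability <- function(r_fold, r_unfold) {
  stopifnot(all(r_fold >= 0), all(r_unfold >= 0))
  if (any(r_fold + r_unfold == 0))
    stop("folding probability undefined when both rates are zero",
         call. = FALSE)
  r_fold / (r_fold + r_unfold)
}

#' Empirical folded fraction of a trace
#'
#' Fraction of samples labelled folded; the time-average estimator of the
#' folding probability.
#'
#' @param states A `state_sequence`.
#' @export
folded_fraction <- function(states) {
  stopifnot(inherits(states, "state_sequence"))
  mean(unclass(states) == 1L)
}

#' Rate table constructor
#'
#' Per-force folding/unfolding rates with event counts; the exchange object
#' between trajectory analysis and rate-model fitting.
#'
#' @param force_pN Force grid, pN.
#' @param r_fold_per_s,r_unfold_per_s Rates, 1/s.
#' @param n_fold,n_unfold Event counts behind each rate.
#' @param ci_lo,ci_hi Optional confidence bounds on the rate of interest.
#' @return A `rate_table` data frame.
#' @export
rate_table <- function(force_pN, r_fold_per_s, r_unfold_per_s,
                       n_fold = NA_integer_, n_unfold = NA_integer_,
                       ci_lo = NA_real_, ci_hi = NA_real_) {
  out <- data.frame(force_pN = force_pN,
                    r_fold_per_s = r_fold_per_s,
                    r_unfold_per_s = r_unfold_per_s,
                    n_fold = n_fold, n_unfold = n_unfold,
                    ci_lo = ci_lo, ci_hi = ci_hi)
  structure(out, class = c("rate_table", "data.frame"))
}

#' Coexistence force from a rate table
#'
#' The force at which folding and unfolding rates are equal, found as the
#' linearly interpolated root of `log(r_F / r_U)` against force; a logistic
#' fit of `P_F(F)` (midpoint reported as `f_half_logistic`) is returned
#' alongside.
#'
#' @param rt A [rate_table()].
#' @return List with `f_half` (interpolated root) and `f_half_logistic`.
#' @export
coexistence_force <- function(rt) {
  stopifnot(inherits(rt, "rate_table"))
  ok <- is.finite(rt$r_fold_per_s) & is.finite(rt$r_unfold_per_s) &
    rt$r_fold_per_s > 0 & rt$r_unfold_per_s > 0
  d <- rt[ok, , drop = FALSE]
  lr <- log(d$r_fold_per_s / d$r_unfold_per_s)
  sgn <- sign(lr)
  ix <- which(sgn[-1] != sgn[-length(sgn)])
  if (!length(ix))
    stop("log rate ratio does not change sign over the force grid",
         call. = FALSE)
  i <- ix[1]
  f_half <- d$force_pN[i] + (0 - lr[i]) *
    (d$force_pN[i + 1] - d$force_pN[i]) / (lr[i + 1] - lr[i])
  pf <- folding_probability(d$r_fold_per_s, d$r_unfold_per_s)
  fit <- try(stats::glm(pf ~ d$force_pN, family = stats::quasibinomial()),
             silent = TRUE)
  f_logi <- if (inherits(fit, "try-error")) NA_real_
            else unname(-stats::coef(fit)[1] / stats::coef(fit)[2])
  list(f_half = f_half, f_half_logistic = f_logi)
}

#' Step sizes at transitions
#'
#' For each state transition, the extension step measured as the difference
#' of median extensions over windows flanking the transition, paired with
#' the force at the transition. Windows truncated by the trace edge are
#' shortened and flagged.
#'
#' @param traj A `mt_trajectory`.
#' @param states The matching `state_sequence`.
#' @param window Flanking window length, s (default 0.5).
#' @return Data frame with `time_s`, `force_pN`, `step_nm`, `direction`,
#'   `truncated`.
#' @export
measure_steps <- function(traj, states, window = 0.5) {
  stopifnot(inherits(traj, "mt_trajectory"),
            inherits(states, "state_sequence"))
  s <- as.vector(unclass(states))
  tr <- which(diff(s) != 0)
  if (!length(tr)) stop("no transitions in trace", call. = FALSE)
  sr <- attr(traj, "sample_rate")
  w <- max(1L, round(window * sr))
  n <- nrow(traj)
  # flanking windows never cross into neighbouring dwells, so fast
  # back-to-back transitions do not contaminate the medians
  run_start <- c(1L, tr + 1L)
  run_end <- c(tr, n)
  out <- lapply(seq_along(tr), function(k) {
    i <- tr[k]
    pre <- max(run_start[k], i - w + 1L):i
    post <- (i + 1L):min(run_end[k + 1L], i + w)
    data.frame(time_s = traj$time_s[i],
               force_pN = traj$force_pN[i],
               step_nm = stats::median(traj$extension_nm[post]) -
                         stats::median(traj$extension_nm[pre]),
               direction = if (s[i + 1L] > s[i]) "unfold" else "fold",
               truncated = length(pre) < w || length(post) < w)
  })
  do.call(rbind, out)
}

#' Write / read dwell tables and rate tables as CSV
#'
#' Fixed headers: `state,start_s,duration_s,censored` and
#' `force_pN,r_fold_per_s,r_unfold_per_s,n_fold,n_unfold,ci_lo,ci_hi`.
#'
#' @param x Table to write.
#' @param path File path.
#' @rdname table_io
#' @export
write_dwell_table <- function(x, path) {
  stopifnot(inherits(x, "dwell_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_dwell_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("state", "start_s", "duration_s", "censored")
  if (!all(need %in% names(df)))
    stop("not a dwell table: missing columns", call. = FALSE)
  structure(df, class = c("dwell_table", "data.frame"))
}

#' @rdname table_io
#' @export
write_rate_table <- function(x, path) {
  stopifnot(inherits(x, "rate_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_rate_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("force_pN", "r_fold_per_s", "r_unfold_per_s")
  if (!all(need %in% names(df)))
    stop("not a rate table: missing columns", call. = FALSE)
  structure(df, class = c("rate_table", "data.frame"))
}
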