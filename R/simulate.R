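#' Simulation configuration
#'
#' Settings for overdamped Langevin dynamics. The integration step defaults
#' to `0.02 * kT / (D * max|U''|)`, with the maximum curvature taken from a
#' dense grid scan of the potential over the simulation domain; the
#' stability requirement `dt * D * max|U''| / kT < 0.1` is enforced before
#' any stepping.
#'
#' @param D Diffusion coefficient along the pulling coordinate, nm^2/s.
#'   The default (5e4) puts tens of folding/unfolding transitions per second
#'   at coexistence for the default landscape; `D` only sets the time scale,
#'   so fitted attempt frequencies scale linearly with it while landscape
#'   shape parameters do not depend on it.
#' @param duration Simulated time, s.
#' @param dt Integration step, s; `NULL` for the automatic choice.
#' @param sample_rate Output sampling rate, Hz (decimation of the raw
#'   integration grid; must not exceed `1/dt`).
#' @param seed Master integer seed. Each trajectory/replicate derives its own
#'   counter-based generator from (seed, replicate index).
#' @param initial Initial position: `"folded"`, `"unfolded"`, or a numeric
#'   position in nm.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(D = 5e4, duration = 1, dt = NULL, sample_rate = 1000,
                       seed = 1L, initial = "folded") {
  stopifnot(D > 0, duration > 0, is.null(dt) || dt > 0, sample_rate > 0)
  if (!is.null(dt) && sample_rate > 1 / dt + 1e-9)
    stop("sample_rate must not exceed 1/dt", call. = FALSE)
  structure(list(D = D, duration = duration, dt = dt,
                 sample_rate = sample_rate, seed = as.integer(seed),
                 initial = initial),
            class = "sim_config")
}

#' Force protocol
#'
#' The three experimental force-application modes of magnetic tweezers, plus
#' an explicit schedule: constant force, linear force ramp, force jump
#' between two levels, or a piecewise-linear `(time, force)` schedule.
#' During ramps the force is updated every integration step.
#'
#' @param mode One of `"constant"`, `"ramp"`, `"jump"`, `"schedule"`.
#' @param F0 Initial/constant force, pN.
#' @param F1 Post-jump force, pN (jump mode).
#' @param rate Loading rate, pN/s (ramp mode; > 0 for unfolding ramps).
#' @param jump_time Time of the jump, s.
#' @param times,forces Schedule node vectors (schedule mode).
#' @return An object of class `force_protocol`.
#' @export
force_protocol <- function(mode = c("constant", "ramp", "jump", "schedule"),
                           F0 = 0, F1 = NULL, rate = NULL, jump_time = NULL,
                           times = NULL, forces = NULL) {
  mode <- match.arg(mode)
  stopifnot(F0 >= 0)
  if (mode == "ramp") stopifnot(!is.null(rate), rate != 0)
  if (mode == "jump") stopifnot(!is.null(F1), F1 >= 0, !is.null(jump_time))
  if (mode == "schedule") {
    stopifnot(!is.null(times), !is.null(forces),
              length(times) == length(forces), all(diff(times) > 0),
              all(forces >= 0))
  }
  structure(list(mode = mode, F0 = F0, F1 = F1, rate = rate,
                 jump_time = jump_time, times = times, forces = forces),
            class = "force_protocol")
}

protocol_mode_code <- function(protocol) {
  match(protocol$mode, c("constant", "ramp", "jump", "schedule")) - 1L
}

protocol_force_range <- function(protocol, duration) {
  switch(protocol$mode,
    constant = c(protocol$F0, protocol$F0),
    ramp = sort(c(protocol$F0, protocol$F0 + protocol$rate * duration)),
    jump = range(protocol$F0, protocol$F1),
    schedule = range(protocol$forces))
}

#' Harmonic test potential
#'
#' `U(z) = kappa z^2 / 2`; mainly for validating the integrator against
#' closed-form equilibrium statistics.
#'
#' @param kappa Stiffness, pN/nm.
#' @param kT Thermal energy, pN.nm.
#' @export
harmonic_potential <- function(kappa, kT = default_kT()) {
  stopifnot(kappa > 0, kT > 0)
  structure(list(kappa = kappa, kT = kT), class = "harmonic_potential")
}

#' Flat test potential
#'
#' Free diffusion; for validating the integrator against the diffusion law.
#'
#' @param kT Thermal energy, pN.nm.
#' @export
flat_potential <- function(kT = default_kT()) {
  structure(list(kT = kT), class = "flat_potential")
}

# Internal: map a potential object to the C++ representation plus a default
# simulation domain. `fmax` is the largest protocol force, used to place the
# upper reflecting wall for landscapes where the WLC tail would otherwise
# force an absurdly small time step: the wall sits where the chain's
# restoring force exceeds the applied force by 15 pN, an essentially
# unreachable extension.
resolve_potential <- function(p, fmax = 0) {
  if (inherits(p, "landscape_params")) {
    zhi <- min(wlc_extension(fmax + 15, p$polymer), 0.95 * p$polymer$dLC)
    zhi <- max(zhi, 0.55 * p$polymer$dLC)
    list(type = 2L,
         params = c(p$U0, p$a, p$G, p$z0, p$s, p$polymer$lP, p$polymer$dLC,
                    p$polymer$kT, as.numeric(p$morse_squared)),
         kT = p$polymer$kT, domain = c(0, zhi))
  } else if (inherits(p, "harmonic_potential")) {
    sd <- sqrt(p$kT / p$kappa)
    list(type = 1L, params = c(p$kappa), kT = p$kT, domain = c(-12, 12) * sd)
  } else if (inherits(p, "flat_potential")) {
    list(type = 0L, params = numeric(1), kT = p$kT, domain = NULL)
  } else stop("unsupported potential object", call. = FALSE)
}

# max |U''| over the domain, by dense-grid central differences of the
# analytic gradient (landscape) or closed form (harmonic/flat).
max_curvature <- function(pot, p, domain, fref = 0) {
  if (pot$type == 0L) return(0)
  if (pot$type == 1L) return(pot$params[1])
  z <- seq(max(domain[1], 1e-6), domain[2], length.out = 4000)
  h <- 1e-4
  g1 <- potential_gradient(pmax(z - h, 0), p)
  g2 <- potential_gradient(z + h, p)
  max(abs((g2 - g1) / (2 * h)))
}

resolve_dt <- function(cfg, pot, p, domain, fref = 0) {
  maxk <- max_curvature(pot, p, domain, fref)
  dt <- cfg$dt
  if (is.null(dt)) {
    if (maxk <= 0)
      stop("dt must be given explicitly for a flat potential", call. = FALSE)
    dt <- 0.02 * pot$kT / (cfg$D * maxk)
  }
  if (maxk > 0 && dt * cfg$D * maxk / pot$kT >= 0.1)
    stop(sprintf(
      "unstable configuration: dt * D * max|U''| / kT = %.3g >= 0.1",
      dt * cfg$D * maxk / pot$kT), call. = FALSE)
  dt
}

resolve_initial <- function(initial, p, f0) {
  if (is.numeric(initial)) return(initial)
  if (!inherits(p, "landscape_params"))
    stop("named initial positions require a landscape potential",
         call. = FALSE)
  p0 <- p; p0$force <- f0
  ex <- find_extrema(p0)
  if (identical(initial, "folded")) {
    if (is.null(ex$folded_min)) stop("no folded minimum at F0", call. = FALSE)
    return(unname(ex$folded_min["position"]))
  }
  if (identical(initial, "unfolded")) {
    if (!is.null(ex$unfolded_min)) return(unname(ex$unfolded_min["position"]))
    return(wlc_extension(max(f0, 0.5), p$polymer))
  }
  stop("initial must be numeric, 'folded' or 'unfolded'", call. = FALSE)
}

#' Run overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of
#' `dz = -(D/kT) U'(z; F(t)) dt + sqrt(2 D dt) xi` with reflecting
#' boundaries, decimated to the configured sampling rate. Identical inputs
#' (including the seed) give bit-identical trajectories.
#'
#' @param p A [landscape_params()], [harmonic_potential()] or
#'   [flat_potential()].
#' @param protocol A [force_protocol()].
#' @param cfg A [sim_config()].
#' @param domain Optional length-2 numeric simulation domain (reflecting
#'   walls); defaults to `[0, zhi]` for landscapes (see Details in
#'   [sim_config()]) and must be given for flat potentials.
#' @param replicate Replicate index combined with `cfg$seed` to seed the
#'   per-trajectory generator.
#' @return A `mt_trajectory`: data frame with columns `time_s`, `force_pN`,
#'   `extension_nm` and attributes `sample_rate` and `provenance`.
#' @export
run_langevin <- function(p, protocol, cfg, domain = NULL, replicate = 1L) {
  stopifnot(inherits(protocol, "force_protocol"),
            inherits(cfg, "sim_config"))
  fr <- protocol_force_range(protocol, cfg$duration)
  pot <- resolve_potential(p, fmax = fr[2])
  if (is.null(domain)) domain <- pot$domain
  if (is.null(domain))
    stop("domain must be supplied for this potential", call. = FALSE)
  dt <- resolve_dt(cfg, pot, p, domain, fref = fr[1])
  decim <- max(1L, as.integer(round(1 / (dt * cfg$sample_rate))))
  nsteps <- floor(cfg$duration / dt)
  z0 <- resolve_initial(cfg$initial, p, protocol$F0)
  proto_params <- c(protocol$F0,
                    if (is.null(protocol$F1)) 0 else protocol$F1,
                    if (is.null(protocol$rate)) 0 else protocol$rate,
                    if (is.null(protocol$jump_time)) 0 else protocol$jump_time)
  res <- cpp_langevin(pot$type, pot$params, z0, dt, nsteps, decim,
                      cfg$D, pot$kT,
                      protocol_mode_code(protocol), proto_params,
                      if (is.null(protocol$times)) numeric(0) else protocol$times,
                      if (is.null(protocol$forces)) numeric(0) else protocol$forces,
                      domain[1], domain[2],
                      cfg$seed, as.integer(replicate))
  traj <- data.frame(time_s = res$time, force_pN = res$force,
                     extension_nm = res$extension)
  structure(traj,
            class = c("mt_trajectory", "data.frame"),
            sample_rate = 1 / (dt * decim),
            provenance = list(potential = p, protocol = protocol, cfg = cfg,
                              domain = domain, dt = dt,
                              replicate = as.integer(replicate)))
}

#' Measurement-chain model
#'
#' Camera noise plus polynomial smoothing, emulating experimental
#' recordings: i.i.d. Gaussian noise added to the extension, followed
#' optionally by a Savitzky-Golay filter.
#'
#' @param noise_sd Noise standard deviation, nm (1.5 nm is typical of
#'   magnetic tweezers recordings).
#' @param smoother `"none"` or `"savitzky_golay"`.
#' @param sg_order Polynomial order of the filter.
#' @param sg_window Window length in samples (odd, > `sg_order`).
#' @export
measurement_model <- function(noise_sd = 1.5,
                              smoother = c("savitzky_golay", "none"),
                              sg_order = 4, sg_window = 51) {
  smoother <- match.arg(smoother)
  stopifnot(noise_sd >= 0)
  if (smoother == "savitzky_golay")
    stopifnot(sg_window %% 2 == 1, sg_window > sg_order)
  structure(list(noise_sd = noise_sd, smoother = smoother,
                 sg_order = sg_order, sg_window = sg_window),
            class = "measurement_model")
}

#' Apply the measurement chain to a trajectory
#'
#' Adds Gaussian noise to the extension channel and applies the configured
#' smoother. The input trajectory is not modified.
#'
#' @param traj A `mt_trajectory`.
#' @param m A [measurement_model()].
#' @param seed Integer seed for the noise.
#' @return A new `mt_trajectory`.
#' @export
emulate_measurement <- function(traj, m, seed = 1L) {
  stopifnot(inherits(traj, "mt_trajectory"), inherits(m, "measurement_model"))
  n <- nrow(traj)
  x <- traj$extension_nm
  if (m$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    x <- x + stats::rnorm(n, sd = m$noise_sd)
  }
  if (m$smoother == "savitzky_golay") {
    if (m$sg_window >= n)
      stop("smoothing window must be shorter than the trajectory",
           call. = FALSE)
    x <- signal::sgolayfilt(x, p = m$sg_order, n = m$sg_window)
  }
  out <- traj
  out$extension_nm <- x
  attr(out, "provenance") <- c(attr(traj, "provenance"),
                               list(measurement = m, measurement_seed = seed))
  out
}

#' Sample first-passage times by direct simulation
#'
#' Runs `n` independent Langevin trajectories at constant force from
#' `start` until absorption at `absorb` (reflecting at `reflect`), and
#' returns the absorption times. Per-replicate generators are derived
#' deterministically from `cfg$seed`, so the sample set does not depend on
#' evaluation order.
#'
#' @param p A [landscape_params()] (or test potential).
#' @param force Constant applied force, pN.
#' @param cfg A [sim_config()] (its `duration` is ignored).
#' @param start Starting position, nm.
#' @param absorb Absorbing boundary, nm (either side of `start`).
#' @param n Number of events.
#' @param reflect Reflecting boundary on the far side of `start` from
#'   `absorb`; defaults to 0 for forward (unfolding) passages and to the
#'   landscape's upper wall for return (refolding) passages.
#' @param max_steps Safety cap on steps per event.
#' @param seed_base Offset added to replicate indices (use to make several
#'   calls draw disjoint replicate streams from one master seed).
#' @return Numeric vector of `n` first-passage times, s.
#' @export
first_passage_times <- function(p, force, cfg, start, absorb, n,
                                reflect = NULL, max_steps = 1e11,
                                seed_base = 0L) {
  pot <- resolve_potential(p, fmax = force)
  if (is.null(reflect)) {
    if (is.null(pot$domain))
      stop("reflect must be supplied for this potential", call. = FALSE)
    reflect <- if (absorb > start) pot$domain[1] else pot$domain[2]
  }
  domain <- sort(c(reflect, absorb))
  dt <- resolve_dt(cfg, pot, p, domain, fref = force)
  cpp_first_passage(pot$type, pot$params, force, start, absorb, reflect,
                    dt, cfg$D, pot$kT, as.integer(n),
                    cfg$seed, as.integer(seed_base), max_steps)
}

#' @export
print.mt_trajectory <- function(x, ...) {
  cat(sprintf(
    "mt_trajectory: %d samples at %.6g Hz, %.4g s, force %.4g-%.4g pN\n",
    nrow(x), attr(x, "sample_rate"), max(x$time_s),
    min(x$force_pN), max(x$force_pN)))
  invisible(x)
}

#' Write a trajectory as CSV with a sidecar metadata block
#'
#' Canonical trajectory format: `#`-prefixed `key: value` metadata lines
#' followed by a CSV table with header `time_s,force_pN,extension_nm`.
#'
#' @param traj A `mt_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mt_trajectory"))
  prov <- attr(traj, "provenance")
  meta <- c(sprintf("# sample_rate_hz: %.10g", attr(traj, "sample_rate")))
  if (!is.null(prov$cfg))
    meta <- c(meta,
              sprintf("# seed: %d", prov$cfg$seed),
              sprintf("# D_nm2_per_s: %.10g", prov$cfg$D),
              sprintf("# dt_s: %.10g", prov$dt),
              sprintf("# replicate: %d", prov$replicate))
  if (inherits(prov$potential, "landscape_params")) {
    p <- prov$potential
    meta <- c(meta, sprintf(
      "# landscape: U0=%g a=%g G=%g z0=%g s=%g lP=%g dLC=%g kT=%g morse_squared=%s",
      p$U0, p$a, p$G, p$z0, p$s, p$polymer$lP, p$polymer$dLC, p$polymer$kT,
      p$morse_squared))
  }
  if (!is.null(prov$protocol))
    meta <- c(meta, sprintf("# protocol: %s", prov$protocol$mode))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path Input file.
#' @return A `mt_trajectory` (metadata in attribute `metadata`).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^#", lines)
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  if (!length(body) || !grepl("^time_s,force_pN,extension_nm", body[1]))
    stop(sprintf("malformed trajectory file %s: expected header at line %d",
                 path, length(meta_idx) + 1), call. = FALSE)
  df <- utils::read.csv(textConnection(body))
  for (col in names(df))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop(sprintf("malformed trajectory file %s: bad record at line %d",
                 path, length(meta_idx) + 1 + bad[1]), call. = FALSE)
  meta <- sub("^#\\s*", "", lines[meta_idx])
  sr <- suppressWarnings(as.numeric(
    sub("sample_rate_hz:\\s*", "", grep("^sample_rate_hz:", meta, value = TRUE))))
  if (!length(sr) || is.na(sr))
    sr <- 1 / stats::median(diff(df$time_s))
  structure(df, class = c("mt_trajectory", "data.frame"),
            sample_rate = sr, metadata = meta)
}
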