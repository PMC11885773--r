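# shared fixtures built in code

protein_l <- function() wlc_model(lP = 0.58, dLC = 18.6, kT = 4.11)

fig3d_landscape <- function(force = 0, morse_squared = FALSE)
  landscape_params(U0 = 50, a = 1, G = 10, z0 = 2, s = 1,
                   polymer = wlc_model(lP = 0.58, dLC = 19, kT = 4.11),
                   force = force, morse_squared = morse_squared)

# construct an mt_trajectory from an extension vector
make_traj <- function(extension, sample_rate = 1000, force = 0) {
  n <- length(extension)
  structure(data.frame(time_s = seq_len(n) / sample_rate,
                       force_pN = rep_len(force, n),
                       extension_nm = extension),
            class = c("mt_trajectory", "data.frame"),
            sample_rate = sample_rate,
            provenance = list())
}

# clean two-state telegraph signal: `dwell` seconds per state, starting folded
telegraph_traj <- function(n_states = 3, dwell = 1, sample_rate = 1000,
                           lo = 0, hi = 15) {
  per <- round(dwell * sample_rate)
  lv <- rep(c(lo, hi), length.out = n_states)
  make_traj(rep(lv, each = per), sample_rate)
}

make_dwells <- function(state, duration, censored = FALSE) {
  structure(data.frame(state = state,
                       start_s = cumsum(c(0, duration[-length(duration)])),
                       duration_s = duration,
                       censored = rep_len(censored, length(duration))),
            class = c("dwell_table", "data.frame"))
}

# Boltzmann CDF of the landscape on [0, zhi] by trapezoid quadrature
boltzmann_cdf <- function(p, zhi, n = 20001) {
  z <- seq(0, zhi, length.out = n)
  u <- total_potential(z, p)
  w <- exp(-(u - min(u)) / p$polymer$kT)
  cw <- cumsum((w[-1] + w[-n]) / 2 * diff(z))
  list(z = z[-1], cdf = cw / cw[n - 1])
}
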