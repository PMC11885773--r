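#' Force-tilted free-energy landscape of a protein under load
#'
#' Parameter container for the one-dimensional free-energy landscape along
#' the pulling coordinate `z` (end-to-end extension):
#' a Morse-like folded well `U0 * (1 - exp(-a z))`, a Gaussian barrier
#' `G * exp(-(z - z0)^2 / s)`, the entropic WLC tail of the unfolded chain,
#' and the linear force tilt `-F z`. The domain is `[0, dLC)`; `z = 0` acts
#' as a hard reflecting wall (the Morse-like term as written is unbounded
#' below for `z < 0`), and is reported as the folded minimum whenever the
#' gradient at `0+` is positive.
#'
#' @param U0 Depth scale of the folded well, pN.nm (> 0).
#' @param a Inverse length scale of the folded well, 1/nm (> 0).
#' @param G Gaussian barrier height, pN.nm (>= 0).
#' @param z0 Barrier position, nm (> 0, < `polymer$dLC`).
#' @param s Gaussian barrier width parameter, nm^2 (> 0). The exponent is
#'   implemented literally as `(z - z0)^2 / s`.
#' @param polymer A [wlc_model()] describing the unfolded chain.
#' @param force Applied force, pN (>= 0).
#' @param morse_squared If `TRUE`, use the squared-Morse variant
#'   `U0 * (1 - exp(-a z))^2` for the folded well (sensitivity analysis;
#'   default `FALSE`).
#' @return An object of class `landscape_params`.
#' @examples
#' p <- landscape_params(polymer = wlc_model(lP = 0.58, dLC = 19))
#' find_extrema(p)
#' @export
landscape_params <- function(U0 = 50, a = 1, G = 10, z0 = 2, s = 1,
                             polymer = wlc_model(lP = 0.58, dLC = 19),
                             force = 0, morse_squared = FALSE) {
  stopifnot(inherits(polymer, "wlc_model"),
            U0 > 0, a > 0, G >= 0, z0 > 0, s > 0, force >= 0,
            z0 < polymer$dLC)
  structure(list(U0 = U0, a = a, G = G, z0 = z0, s = s,
                 polymer = polymer, force = force,
                 morse_squared = isTRUE(morse_squared)),
            class = "landscape_params")
}

#' @export
print.landscape_params <- function(x, ...) {
  cat(sprintf(
    "Landscape: U0 = %g pN.nm, a = %g /nm, G = %g pN.nm, z0 = %g nm, s = %g nm^2%s\n",
    x$U0, x$a, x$G, x$z0, x$s,
    if (x$morse_squared) " (squared Morse)" else ""))
  cat(sprintf("  force = %g pN; ", x$force))
  print(x$polymer)
  invisible(x)
}

#' Free energy of the stretched unfolded chain
#'
#' Integral of the WLC force-extension relation, tilted by the applied
#' force: `(kT/lP) * (-dLC^2 / (4 (z - dLC)) + z^2 / (2 dLC) - z/4) - F z`.
#' Its `z`-derivative at `F = 0` is [wlc_force()].
#'
#' @param z Extension, nm; vectorised; `0 <= z < dLC`.
#' @param polymer A [wlc_model()].
#' @param force Applied force, pN.
#' @return Free energy in pN.nm.
#' @export
unfolded_free_energy <- function(z, polymer, force = 0) {
  stopifnot(inherits(polymer, "wlc_model"))
  if (any(z < 0 | z >= polymer$dLC))
    stop("z must lie in [0, dLC)", call. = FALSE)
  dLC <- polymer$dLC
  (polymer$kT / polymer$lP) *
    (-0.25 * dLC^2 / (z - dLC) + z^2 / (2 * dLC) - 0.25 * z) - force * z
}

#' Total landscape potential
#'
#' Sum of the Morse-like folded well, the Gaussian barrier, the unfolded
#' chain's entropic free energy, and the force tilt.
#'
#' @param z Extension, nm; vectorised; `0 <= z < dLC`.
#' @param p A [landscape_params()].
#' @return Potential energy in pN.nm.
#' @export
total_potential <- function(z, p) {
  stopifnot(inherits(p, "landscape_params"))
  if (any(z < 0 | z >= p$polymer$dLC))
    stop("z must lie in [0, dLC)", call. = FALSE)
  m <- 1 - exp(-p$a * z)
  morse <- if (p$morse_squared) p$U0 * m^2 else p$U0 * m
  morse + p$G * exp(-(z - p$z0)^2 / p$s) +
    unfolded_free_energy(z, p$polymer, force = p$force)
}

#' Analytic gradient of the landscape potential
#'
#' @param z Extension, nm; vectorised; `0 <= z < dLC`.
#' @param p A [landscape_params()].
#' @return dU/dz in pN.
#' @export
potential_gradient <- function(z, p) {
  stopifnot(inherits(p, "landscape_params"))
  if (any(z < 0 | z >= p$polymer$dLC))
    stop("z must lie in [0, dLC)", call. = FALSE)
  e <- exp(-p$a * z)
  dm <- if (p$morse_squared) 2 * p$U0 * p$a * e * (1 - e) else p$U0 * p$a * e
  dm - 2 * p$G * (z - p$z0) / p$s * exp(-(z - p$z0)^2 / p$s) +
    wlc_force(z, p$polymer) - p$force
}

# Locate interior extrema of f on [lower, upper] by sign changes of the
# numerical gradient on a grid, refined by golden-section (stats::optimize).
find_extrema_fn <- function(f, lower, upper, grid_step = 0.01,
                            refine_tol = 1e-6) {
  zg <- seq(lower, upper, by = grid_step)
  if (zg[length(zg)] < upper) zg <- c(zg, upper)
  u <- f(zg)
  d <- diff(u)
  n <- length(d)
  sgn <- sign(d)
  mins <- list(); maxs <- list()
  idx <- which(sgn[-n] > 0 & sgn[-1] < 0)
  for (i in idx) {
    lo <- zg[max(i - 1, 1)]; hi <- zg[min(i + 2, length(zg))]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = refine_tol)
    maxs[[length(maxs) + 1]] <- c(position = opt$maximum, energy = opt$objective)
  }
  idx <- which(sgn[-n] < 0 & sgn[-1] > 0)
  for (i in idx) {
    lo <- zg[max(i - 1, 1)]; hi <- zg[min(i + 2, length(zg))]
    opt <- stats::optimize(f, c(lo, hi), maximum = FALSE, tol = refine_tol)
    mins[[length(mins) + 1]] <- c(position = opt$minimum, energy = opt$objective)
  }
  # boundary minimum at the left wall when the gradient there is positive
  if (d[1] > 0)
    mins <- c(list(c(position = lower, energy = u[1])), mins)
  list(minima = mins, maxima = maxs)
}

#' Locate minima and barrier of the landscape
#'
#' Scans the potential on a grid over `[0, dLC - eps]`, locates local
#' extrema by sign changes of the numerical gradient, and refines them by
#' golden-section search to 1e-6 nm. The domain boundary `z = 0` is reported
#' as the folded minimum when the gradient is positive there. A monotonic
#' landscape yields absent barrier/unfolded entries, not an error.
#'
#' @param p A [landscape_params()], or an arbitrary potential function of
#'   `z` (in which case `domain` must be given).
#' @param grid_step Scan resolution, nm (default 0.01).
#' @param domain Numeric length-2 vector; required when `p` is a function.
#' @return An object of class `landscape_extrema`: list with `folded_min`,
#'   `barrier`, `unfolded_min` (each `c(position, energy)` or `NULL`),
#'   `dG_unfold` (barrier - folded), `dG_fold` (barrier - unfolded) and
#'   `dG_eq` (unfolded - folded), the last two `NA` when the unfolded
#'   minimum is absent.
#' @export
find_extrema <- function(p, grid_step = 0.01, domain = NULL) {
  if (inherits(p, "landscape_params")) {
    f <- function(z) total_potential(z, p)
    lower <- 0
    upper <- p$polymer$dLC * (1 - 1e-4)
  } else if (is.function(p)) {
    if (is.null(domain) || length(domain) != 2)
      stop("custom potential requires a length-2 'domain'", call. = FALSE)
    f <- p
    lower <- domain[1]; upper <- domain[2]
  } else stop("p must be landscape_params or a function", call. = FALSE)

  ex <- find_extrema_fn(f, lower, upper, grid_step)
  mins <- ex$minima; maxs <- ex$maxima
  folded <- if (length(mins)) mins[[1]] else NULL
  barrier <- NULL; unfolded <- NULL
  if (!is.null(folded) && length(maxs)) {
    after <- Filter(function(m) m["position"] > folded["position"], maxs)
    if (length(after)) {
      barrier <- after[[1]]
      beyond <- Filter(function(m) m["position"] > barrier["position"], mins)
      if (length(beyond))
        unfolded <- beyond[[which.min(vapply(beyond, `[`, 0, "energy"))]]
    }
  }
  structure(list(
    folded_min = folded, barrier = barrier, unfolded_min = unfolded,
    dG_unfold = if (!is.null(barrier) && !is.null(folded))
      unname(barrier["energy"] - folded["energy"]) else NA_real_,
    dG_fold = if (!is.null(barrier) && !is.null(unfolded))
      unname(barrier["energy"] - unfolded["energy"]) else NA_real_,
    dG_eq = if (!is.null(unfolded) && !is.null(folded))
      unname(unfolded["energy"] - folded["energy"]) else NA_real_
  ), class = "landscape_extrema")
}

#' @export
print.landscape_extrema <- function(x, ...) {
  pe <- function(nm, v) {
    if (is.null(v)) cat(sprintf("  %-12s absent\n", nm))
    else cat(sprintf("  %-12s z = %8.4f nm, U = %9.4f pN.nm\n",
                     nm, v["position"], v["energy"]))
  }
  cat("Landscape extrema:\n")
  pe("folded", x$folded_min); pe("barrier", x$barrier)
  pe("unfolded", x$unfolded_min)
  cat(sprintf("  dG_unfold = %.4g, dG_fold = %.4g, dG_eq = %.4g pN.nm\n",
              x$dG_unfold, x$dG_fold, x$dG_eq))
  invisible(x)
}

# Curvature |U''| by local quadratic least-squares fit over +/- half_width,
# clipped to the domain. Works for tabulated/custom potentials too.
local_curvature <- function(f, z, half_width = 0.2, lower = -Inf, upper = Inf) {
  lo <- max(z - half_width, lower); hi <- min(z + half_width, upper)
  zz <- seq(lo, hi, length.out = 41)
  co <- stats::lm.fit(cbind(1, zz - z, (zz - z)^2), f(zz))$coefficients
  2 * co[3]
}

#' Kramers escape rate over the landscape barrier
#'
#' Overdamped high-barrier escape rate
#' `(D / (2 pi kT)) * sqrt(k_well * k_barrier) * exp(-dG / kT)`, with the
#' well and barrier curvatures estimated by local quadratic least-squares
#' fits over +/- 0.2 nm. The curvature factor enters as the square root of
#' the product of the curvature magnitudes (the standard overdamped Kramers
#' prefactor).
#'
#' @param p A [landscape_params()].
#' @param D Diffusion coefficient along `z`, nm^2/s.
#' @param direction `"unfold"` (folded to unfolded) or `"fold"`.
#' @return Escape rate in 1/s.
#' @export
kramers_rate <- function(p, D, direction = c("unfold", "fold")) {
  direction <- match.arg(direction)
  stopifnot(inherits(p, "landscape_params"), D > 0)
  ex <- find_extrema(p)
  if (is.null(ex$barrier))
    stop("no barrier: Kramers rate undefined", call. = FALSE)
  well <- if (direction == "unfold") ex$folded_min else ex$unfolded_min
  if (is.null(well))
    stop("required minimum absent: Kramers rate undefined", call. = FALSE)
  dG <- ex$barrier["energy"] - well["energy"]
  f <- function(z) total_potential(z, p)
  kT <- p$polymer$kT
  upper <- p$polymer$dLC * (1 - 1e-4)
  kw <- abs(local_curvature(f, well["position"], lower = 0, upper = upper))
  kb <- abs(local_curvature(f, ex$barrier["position"], lower = 0, upper = upper))
  unname(D / (2 * pi * kT) * sqrt(kw * kb) * exp(-dG / kT))
}

#' Write a landscape as a two-column table
#'
#' Exports `(z_nm, U_pNnm)` as comma-separated text for plotting.
#'
#' @param p A [landscape_params()].
#' @param path Output file.
#' @param n Number of grid points.
#' @export
export_landscape <- function(p, path, n = 1000) {
  z <- seq(0, p$polymer$dLC * (1 - 1e-4), length.out = n)
  utils::write.csv(data.frame(z_nm = z, U_pNnm = total_potential(z, p)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landscape parameters from a key = value config file
#'
#' Plain-text format, one `key = value` per line, `#` comments allowed.
#' Recognised keys: `U0, a, G, z0, s, lP, dLC, kT, force, morse_squared`.
#' Units are fixed package-wide (pN, nm, pN.nm).
#'
#' @param path Config file path.
#' @return A [landscape_params()].
#' @export
read_landscape_config <- function(path) {
  kv <- read_key_values(path)
  num <- function(k, default = NULL) {
    if (!is.null(kv[[k]])) as.numeric(kv[[k]])
    else if (!is.null(default)) default
    else stop(sprintf("config missing key '%s'", k), call. = FALSE)
  }
  landscape_params(
    U0 = num("U0"), a = num("a"), G = num("G"), z0 = num("z0"), s = num("s"),
    polymer = wlc_model(lP = num("lP"), dLC = num("dLC"),
                        kT = num("kT", default_kT())),
    force = num("force", 0),
    morse_squared = isTRUE(as.logical(kv[["morse_squared"]])))
}

# shared flat key = value parser
read_key_values <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  kv
}
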