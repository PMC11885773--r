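#' Default thermal energy
#'
#' Thermal energy kT in pN.nm used throughout the package when a model does
#' not specify one. Defaults to 4.11 pN.nm (about 298 K); override globally
#' with `options(mtfold.kT = ...)`. All energies in the package are in pN.nm
#' (1 pN.nm is approximately 0.2389 kcal/mol; no automatic conversion is
#' performed).
#'
#' @return Thermal energy in pN.nm.
#' @export
default_kT <- function() {
  kT <- getOption("mtfold.kT", 4.11)
  stopifnot(is.numeric(kT), length(kT) == 1L, kT > 0)
  kT
}

#' Worm-like chain polymer model
#'
#' Entropic-elasticity model of an unfolded polypeptide, parameterised by its
#' persistence length and the contour-length change on unfolding (unfolded
#' contour length minus folded size).
#'
#' @param lP Persistence length, nm (> 0). About 0.5-0.6 nm for polypeptides.
#' @param dLC Contour-length change, nm (> 0).
#' @param kT Thermal energy, pN.nm.
#' @return An object of class `wlc_model`.
#' @examples
#' protein_l <- wlc_model(lP = 0.58, dLC = 18.6)
#' wlc_force(9.3, protein_l)
#' @export
wlc_model <- function(lP = 0.58, dLC, kT = default_kT()) {
  stopifnot(is.numeric(lP), lP > 0, is.numeric(dLC), dLC > 0,
            is.numeric(kT), kT > 0)
  structure(list(lP = lP, dLC = dLC, kT = kT), class = "wlc_model")
}

#' @export
print.wlc_model <- function(x, ...) {
  cat(sprintf("WLC model: lP = %g nm, dLC = %g nm, kT = %g pN.nm\n",
              x$lP, x$dLC, x$kT))
  invisible(x)
}

#' Freely-jointed chain polymer model
#'
#' Alternative polymer model parameterised by a Kuhn length; used in the
#' first-passage refolding rate law. FJC fits typically return shorter
#' contour lengths than WLC fits of the same molecule; the two models'
#' parameters are treated as independent.
#'
#' @param lK Kuhn length, nm (> 0).
#' @param dLC Contour-length change, nm (> 0).
#' @param kT Thermal energy, pN.nm.
#' @return An object of class `fjc_model`.
#' @export
fjc_model <- function(lK, dLC, kT = default_kT()) {
  stopifnot(is.numeric(lK), lK > 0, is.numeric(dLC), dLC > 0,
            is.numeric(kT), kT > 0)
  structure(list(lK = lK, dLC = dLC, kT = kT), class = "fjc_model")
}

#' @export
print.fjc_model <- function(x, ...) {
  cat(sprintf("FJC model: lK = %g nm, dLC = %g nm, kT = %g pN.nm\n",
              x$lK, x$dLC, x$kT))
  invisible(x)
}

#' WLC force at a given extension
#'
#' Force required to hold a worm-like chain at extension `z`:
#' `(kT/lP) * (1/4 * (1 - z/dLC)^-2 + z/dLC - 1/4)`. Strictly increasing in
#' `z` and divergent as `z` approaches the contour length.
#'
#' @param z Extension, nm; vectorised. Must satisfy `0 <= z < dLC`.
#' @param model A [wlc_model()].
#' @return Force in pN.
#' @export
wlc_force <- function(z, model) {
  stopifnot(inherits(model, "wlc_model"), is.numeric(z))
  if (any(z < 0 | z >= model$dLC))
    stop("extension must lie in [0, dLC)", call. = FALSE)
  x <- z / model$dLC
  (model$kT / model$lP) * (0.25 * (1 - x)^-2 + x - 0.25)
}

#' WLC extension at a given force
#'
#' Inverts [wlc_force()] on `[0, dLC)` by Brent's bracketing root finder to a
#' relative tolerance of 1e-10. This is the expected unfolding step size at
#' force `F` when the model describes a protein's contour-length change.
#'
#' @param force Force, pN (>= 0); vectorised.
#' @param model A [wlc_model()].
#' @return Extension in nm; `0` at zero force.
#' @export
wlc_extension <- function(force, model) {
  stopifnot(inherits(model, "wlc_model"), is.numeric(force))
  if (any(force < 0)) stop("force must be non-negative", call. = FALSE)
  hi <- model$dLC * (1 - 1e-9)
  vapply(force, function(f) {
    if (f == 0) return(0)
    if (f >= wlc_force(hi, model)) return(hi)
    stats::uniroot(function(z) wlc_force(z, model) - f,
                   lower = 0, upper = hi,
                   tol = 1e-10 * model$dLC)$root
  }, numeric(1))
}

#' FJC extension at a given force
#'
#' Langevin-function extension of a freely-jointed chain,
#' `dLC * (coth(u) - 1/u)` with `u = F * lK / kT`. Monotone in force,
#' saturating at the contour length; returns 0 at zero force (the limit
#' value).
#'
#' @param force Force, pN (>= 0); vectorised.
#' @param model An [fjc_model()].
#' @return Extension in nm.
#' @export
fjc_extension <- function(force, model) {
  stopifnot(inherits(model, "fjc_model"), is.numeric(force))
  if (any(force < 0)) stop("force must be non-negative", call. = FALSE)
  u <- force * model$lK / model$kT
  out <- numeric(length(u))
  small <- u < 1e-4
  # series: coth(u) - 1/u = u/3 - u^3/45 + O(u^5), avoids 0/0 at u = 0
  out[small] <- model$dLC * (u[small] / 3 - u[small]^3 / 45)
  ub <- u[!small]
  out[!small] <- model$dLC * (1 / tanh(ub) - 1 / ub)
  out
}
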