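---
title: "Modelling single-protein folding under force: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-protein folding under force: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtfold)
```

## The physical picture

Magnetic tweezers hold a single protein under a calibrated, essentially
constant force while its end-to-end extension is recorded. Along the pulling
coordinate $z$ the (un)folding reaction is well described by diffusion on a
one-dimensional free-energy profile. `mtfold` builds that profile from four
additive pieces:

$$U(z) = U_0\,(1 - e^{-a z}) \;+\; G\,e^{-(z - z_0)^2/s} \;+\;
  U_{\mathrm{WLC}}(z) \;-\; F z,$$

* a Morse-like attractive well for the folded state, with energy scale
  $U_0$ (pN·nm) and inverse length scale $a$ (nm$^{-1}$);
* a Gaussian barrier of height $G$ (pN·nm) at position $z_0$ (nm) with
  width parameter $s$ (nm$^2$), standing in for the entropic cost of the
  hydrophobic collapse;
* the entropic free energy of the stretched unfolded chain, the integral
  of the worm-like-chain (WLC) force–extension law with persistence length
  $l_P$ and contour-length change $\Delta L_C$:
  $U_{\mathrm{WLC}}(z) = \frac{kT}{l_P}\left[-\frac{\Delta L_C^2}{4(z-\Delta L_C)}
  + \frac{z^2}{2\Delta L_C} - \frac{z}{4}\right]$;
* the mechanical tilt $-Fz$ of the applied force.

The defaults ($U_0 = 50$ pN·nm, $a = 1$ nm$^{-1}$, $G = 10$ pN·nm,
$z_0 = 2$ nm, $s = 1$ nm$^2$, $l_P = 0.58$ nm, $\Delta L_C = 19$ nm,
$kT = 4.11$ pN·nm) describe a protein-L-like two-state folder. At zero
force this landscape has its folded minimum pinned at $z = 0$, an interior
barrier at $z = 2.35$ nm, and an unfolding barrier height of

```{r}
find_extrema(landscape_params())$dG_unfold
```

about 55.5 pN·nm ($\approx 13.5\,kT$). Force tilts the landscape: the
barrier drops, and the unfolded minimum — which sits on the WLC branch —
moves outward in a strongly non-linear way, which is why proteins refold
only in a narrow band of low forces.

Two deliberate domain conventions deserve comment.

* **Domain and the $z=0$ wall.** The Morse-like term as written is
  unbounded below for $z < 0$, so the model is defined on $[0, \Delta L_C)$
  with $z = 0$ a hard reflecting wall, reported as the folded minimum
  whenever the gradient at $0^+$ is positive. This keeps the printed
  functional form intact while making the dynamics well-posed. A
  squared-Morse variant $U_0 (1 - e^{-az})^2$, which is smooth through
  zero, is available behind `morse_squared = TRUE` for sensitivity
  analysis; at zero force it gives a barrier of ≈ 51.6 pN·nm instead of
  55.5.
* **Units of $s$.** The barrier exponent is implemented literally as
  $(z-z_0)^2/s$ with $s$ carrying nm², because that is the only reading
  under which the stated width value is dimensionally coherent; with
  $s = 1$ every plausible reading is numerically identical anyway.

Thermal energy defaults to $kT = 4.11$ pN·nm (≈ 298 K) and can be changed
globally with `options(mtfold.kT = ...)`. All forces are in pN, lengths in
nm, energies in pN·nm (1 pN·nm ≈ 0.2389 kcal/mol; never auto-converted).

## Langevin dynamics and the measurement chain

Trajectories follow the overdamped Euler–Maruyama update
$z \leftarrow z - (D/kT)\,U'(z; F(t))\,dt + \sqrt{2 D\, dt}\,\xi$ with
reflection at both domain edges. Three experimental force protocols are
built in — constant force, linear ramps (force updated every integration
step), and force jumps — plus arbitrary piecewise-linear schedules.

* **Diffusion coefficient.** The overdamped theory leaves the time scale
  free, so $D$ is a parameter. The default $D = 5\times 10^4$ nm²/s puts
  tens of transitions per second at the coexistence force of the default
  landscape, convenient for both simulation and display. All *shape*
  quantities extracted downstream (transition-state distances, barrier
  heights, polymer parameters) are independent of $D$; only attempt
  frequencies $k_0$ scale with it.
* **Time step.** `dt` defaults to $0.02\,kT/(D \max|U''|)$ with the
  maximum curvature taken from a dense grid scan of the simulation domain;
  the construction-time stability check refuses configurations with
  $dt\,D\,\max|U''|/kT \ge 0.1$.
* **Upper wall placement.** The WLC stiffness diverges at $\Delta L_C$,
  which would force an absurdly small `dt` if the domain ran all the way
  to the contour length. The reflecting wall is therefore placed where the
  chain's restoring force exceeds the largest protocol force by 15 pN
  (capped at $0.95\,\Delta L_C$) — an extension whose equilibrium weight
  is negligible, so the truncation does not affect observables.
* **Random numbers.** Each trajectory or first-passage replicate gets its
  own counter-based generator (xoshiro256** seeded through splitmix64 from
  the master seed and the replicate index, with polar-method normals), so
  replicate sets are bit-reproducible and order-independent.
* **Interpolated drift.** The zero-force gradient is tabulated once per
  run on a $2^{14}$-node grid and linearly interpolated; the force tilt
  enters exactly. At this resolution the interpolation error is far below
  the thermal noise, and the table is what makes million-barrier-crossing
  runs affordable.

`emulate_measurement()` reproduces an experimental recording chain:
i.i.d. Gaussian camera noise (default SD 1.5 nm, typical of magnetic
tweezers) followed by a fourth-order Savitzky–Golay filter with a 51-point
window.

## From trajectories to rates

State assignment uses a dual-threshold Schmitt trigger rather than a
single threshold or an HMM: with the two thresholds bracketing the
midpoint between the landscape minima (default band: midpoint ± 25% of the
separation), a 1.5-nm-noise trace cannot chatter across a single
threshold, the labelling is deterministic, and the parameters are
transparent. Dwell times are read off the crossings; the first and last
dwells are flagged censored and contribute to rate denominators but not
event counts (the standard survival-analysis treatment, which keeps rates
unbiased on short traces). Rates are exponential MLEs with chi-square 95%
intervals; with zero events only a one-sided upper bound is reported.
Step sizes use medians over 0.5-s flanking windows to resist drift and
smoothing transients. The folding probability is
$P_F = r_F/(r_F + r_U)$, and the coexistence force $F_{1/2}$ is the
interpolated root of $\log(r_F/r_U)$ (a logistic-fit midpoint is reported
alongside).

For simulated rate-versus-force curves the package samples first-passage
events directly (folded minimum → unfolded minimum for unfolding, the
mirror for refolding, scored 0.05 nm from the target minimum) rather than
segmenting equilibrium traces: it needs no thresholds, extends to forces
where one branch is unobservably slow, and its exact expectation — the 1-D
mean-first-passage-time double integral, provided as `mfpt()` — makes it
directly testable. Threshold-based analysis of equilibrium traces is kept
as a cross-check; the two agree within sampling error near coexistence.

## Rate laws and fitting

Three force-dependent rate laws are provided: Bell
($r = k_0 e^{F x^\dagger/kT}$), Dudko–Hummer–Szabo with shape parameter
$\nu$ (default $2/3$, the linear-cubic barrier, which approximates most
analytic barriers well; $\nu = 1$ recovers Bell exactly), and the
first-passage freely-jointed-chain refolding law
$r_F = k_0 \exp[-(\Delta L_C/l_K)(\ln|\sinh u| - \ln u)]$, $u = F l_K/kT$,
whose exponent is the FJC extension integrated over force and which is
evaluated stably at large $u$ via $u - \ln 2u + \log(1 - e^{-2u})$.

Fits are weighted least squares on log rate with weights from event counts
($\sigma_{\log r} \approx 1/\sqrt{N}$), Levenberg–Marquardt for the
nonlinear models, and explicit force windows — the Bell fit to unfolding
data is restricted to ≤ 15 pN by default in the integrated pipeline, where
the log-linear approximation holds, while DHS uses the full range. Fitting
the polynomial-barrier models to the refolding branch is permitted (it
yields negative $x^\dagger$, whose physical interpretation is strained —
the refolding barrier both moves and reshapes with force).

Ramp rupture-force distributions use the survival construction
$p(F) = [r(F)/a]\exp[-\frac1a\int_0^F r]$; for the Bell law the hazard
integral is analytic and carries the $k_0 kT/(a x^\dagger)$ prefactor that
dimensional analysis requires. Ramp fitting is by direct maximum
likelihood on the event forces — histogram binning affects only plots. An
independent thinning sampler (`sample_rupture_forces()`) provides the
cross-check distribution.

## What the simulations do and do not establish

The synthetic trajectories emulate: two-state hopping on a realistic
force-tilted landscape, WLC-scaling step sizes, exponential dwell
statistics, camera noise and polynomial smoothing, and the three
experimental protocols. They do not emulate: bead–tether hydrodynamics,
camera motion blur, surface drag, drift, multi-state or misfolded
intermediates, or any orthogonal reaction coordinate. Passing tests
therefore validate the analysis chain on the stated model class, not the
model's adequacy for any particular protein.

Two quantitative caveats surfaced by the package's own validation suite
are worth knowing:

* **Effective transition-state distances are window-dependent.** On the
  default landscape the local force sensitivity
  $kT\,\mathrm d\ln r_U/\mathrm dF$ falls from ≈ 2.3 nm near 5 pN to
  ≈ 1.4 nm at 25 pN, because the barrier position migrates inward under
  load. A Bell fit over 5–15 pN therefore reports $x^\dagger \approx 1.8$
  nm — substantially below both the zero-force barrier position (2.35 nm)
  and values quoted elsewhere for this landscape family. This is a real
  property of the printed potential, reproduced identically by the MFPT
  quadrature oracle, not a sampling artefact.
* **The three-parameter FJC refolding fit is weakly identified.** With
  ~6 forces over 2–10 pN and ~10% rate noise, $(k_0, \Delta L_C, l_K)$
  trade off along a ridge; the reported $\Delta L_C$ scatters by tens of
  percent between realizations even though the fitted curve barely moves.
  Freezing $\Delta L_C$ and $l_K$ at independently measured values — the
  model's intended use, supported via the `frozen` argument — removes the
  degeneracy entirely.

## Numerical choices

* WLC inversion by Brent's bracketing method on $[0, \Delta L_C(1-10^{-9})]$
  to $10^{-10}$ relative tolerance; derivative-free, robust to the
  divergence at the contour length.
* Extremum location by grid scan (default 0.01 nm) with sign changes of
  the numerical gradient, refined by golden-section search to $10^{-6}$ nm;
  a monotonic landscape reports absent extrema rather than failing.
* Kramers-rate curvatures from local quadratic least-squares fits over
  ± 0.2 nm, so tabulated or custom potentials are handled uniformly; the
  prefactor uses the standard overdamped form
  $(D/2\pi kT)\sqrt{\kappa_\cup \kappa_\cap}$.
* MFPT by nested adaptive quadrature at $10^{-6}$ relative tolerance with
  a potential-offset shift to avoid overflow.
* Calibration fits run in observed-step space, not inverted-force space,
  so heteroscedastic step noise propagates correctly (the WLC inversion
  amplifies noise at high force, where step-size sensitivity flattens).

## Problem sizes used in the validation suite

The acceptance-level checks simulate 150 first-passage events at each of
nine unfolding forces (5–25 pN) and six refolding forces (2–10 pN),
Boltzmann-equilibrium comparisons on $10^6$-sample constant-force traces,
500-event MFPT cross-checks, $10^4$-event rupture-force samples, and
100-replicate coverage studies for every fitter. These sizes give ~8%
standard errors on individual rates and sub-2% Kolmogorov–Smirnov
resolution, which is the precision the assertions are written against.

## Known limitations

One-dimensional reaction coordinate only; no catch-bond phenomenology, no
force-dependent diffusion coefficient, no memory kernels; the fluctuation
calibration implements only the time-domain equipartition estimator; the
double-exponential magnet law is provided but off by default; HMM/
multi-state segmentation is out of scope.
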