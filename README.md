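# mtfold

Simulation and analysis of single-protein folding dynamics under mechanical
force, as measured in magnetic tweezers.

Magnetic tweezers hold a protein under a calibrated constant force
(force-clamp) while recording its end-to-end extension; folding and
unfolding appear as stepwise extension changes whose dwell statistics
encode the underlying free-energy landscape. `mtfold` is for
experimentalists and modellers who want to (i) simulate such recordings
from an explicit landscape, (ii) turn recordings — real or simulated —
into states, dwell times, rates, step sizes and folding probabilities, and
(iii) fit the standard force-dependent rate laws and instrument
calibration laws.

## The model

The package's core is a one-dimensional free-energy profile along the
pulling coordinate *z*:

U(z) = U₀(1 − e^(−az)) + G·e^(−(z−z₀)²/s) + (kT/l_P)[−ΔL_C²/(4(z−ΔL_C)) + z²/(2ΔL_C) − z/4] − F·z

— a Morse-like folded well, a Gaussian barrier, the worm-like-chain (WLC)
entropic free energy of the stretched unfolded chain, and the force tilt.
Overdamped Langevin dynamics on this profile (Euler–Maruyama, compiled
core, counter-based per-replicate RNG) generate trajectories under
constant-force, force-ramp and force-jump protocols, with optional
camera-noise + Savitzky–Golay measurement emulation.

Analysis tools include:

* **Polymer elasticity**: WLC force/extension and their inversion, FJC
  extension (`wlc_force`, `wlc_extension`, `fjc_extension`).
* **Landscape**: extremum/barrier location (`find_extrema`), Kramers
  escape rates, exact mean-first-passage-time quadrature (`mfpt`).
* **Trajectory analysis**: Schmitt-trigger state assignment
  (`assign_states`), dwell tables, exponential rate MLEs with chi-square
  CIs, step sizes, folding probability, coexistence force.
* **Rate laws**: Bell r(F) = k₀e^(Fx†/kT), Dudko–Hummer–Szabo, and the
  first-passage FJC refolding law, with weighted log-rate fitting
  (`fit_rates`); rupture-force distributions under force ramps and their
  maximum-likelihood fit (`ramp_pdf`, `fit_ramp`).
* **Calibration**: exponential magnet law, tape-head law, equipartition
  force, and step-size-based calibration fits (`fit_magnet_law`).

## Worked example

Simulate a protein-L-like two-state folder at its coexistence region and
recover its kinetics:

```r
library(mtfold)

p   <- landscape_params(U0 = 50, a = 1, G = 10, z0 = 2, s = 1,
                        polymer = wlc_model(lP = 0.58, dLC = 19))
find_extrema(p)
#> Landscape extrema:
#>   folded       z =   0.0000 nm, U =   33.8426 pN.nm
#>   barrier      z =   2.3493 nm, U =   89.3555 pN.nm
#>   unfolded     z =   3.4209 nm, U =   86.8663 pN.nm
#>   dG_unfold = 55.51, dG_fold = 2.489, dG_eq = 53.02 pN.nm
```

At zero force the unfolding barrier is 55.5 pN·nm (~13.5 kT) with the
transition state 2.35 nm from the folded well. Now sample
first-passage rates across force and fit the rate laws:

```r
cfg <- sim_config(D = 5e4, seed = 1)      # D sets the time scale only
res <- fig3_pipeline(p, cfg, n_events = 100)
res
#> Simulated-landscape rate analysis
#>   15 forces, unfolding 5-25 pN, refolding 2-10 pN
#>   Bell (unfold):   k0 = 1.2 /s, x+ = 1.778 nm
#>   DHS  (unfold):   k0 = 0.791 /s, x+ = 2.278 nm, dG0+ = 43.0 pN.nm
#>   FJC  (refold):   k0 = 4.64e+03 /s, dLC = 36.74 nm, lK = 0.288 nm
```

Reading these numbers: the Bell fit over 5–15 pN reports an effective
transition-state distance of ~1.8 nm — smaller than the zero-force
barrier position because the barrier migrates inward under load (the
local force sensitivity falls from ~2.3 nm at 5 pN to ~1.4 nm at 25 pN).
The DHS fit absorbs part of that curvature and estimates a zero-force
barrier of ~43 pN·nm against the true 55.5. The three-parameter FJC
refolding fit is weakly identified on six forces (note `dLC` here landing
far up its ridge with σ ≈ 69 nm); freeze the independently measurable
polymer parameters for stable attempt-frequency estimates:

```r
fit_rates(res$rate_table, "refold", "fold", c(2, 10),
          frozen = list(dLC = 16.5, lK = 0.8))
```

A single constant-force trace, with the experimental measurement chain:

```r
tr  <- run_langevin(p, force_protocol("constant", F0 = 7),
                    sim_config(duration = 5, sample_rate = 1e4, seed = 2))
obs <- emulate_measurement(tr, measurement_model(noise_sd = 1.5), seed = 3)
th  <- default_thresholds({p$force <- 7; p})
an  <- analyze_trajectory(tr, th[1], th[2])
an$folded_fraction          # empirical P_F at 7 pN
an$rates$unfold$rate        # 1/s, with chi-square CI in $ci
```

A command-line interface (`inst/cli/mtfold`) wraps the same pipelines
(`simulate`, `analyze`, `fig3`, `fit-ramp`, `calibrate`) for shell use.

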