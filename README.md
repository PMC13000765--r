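# petrand

Random coincidence identification and estimation for PET event streams,
including triple coincidences.

## The problem

PET imaging detects pairs of 511 keV annihilation photons ("singles")
that arrive within a coincidence time window τ. At clinical activities,
singles from different decays also fall into the same window and form
*random* coincidences that bias quantitative reconstruction. For
β⁺γ emitters (e.g. ²²Na, used in dual-tracer PET and positronium-lifetime
imaging) the events of interest are *triples* — two annihilation photons
plus a prompt γ — and random triples arise from two or three distinct
decays. Correcting for all of these requires estimators that work from
the measured event stream alone.

petrand provides:

* a statistical Monte Carlo simulator of list-mode singles streams:
  homogeneous-Poisson decays at constant activity A, per-decay detection
  efficiencies (ε₂ both annihilation photons, ε₁ exactly one, ε_γ the
  prompt γ), Gaussian timing jitter with pair FWHM equal to the
  coincidence time resolution, optional non-paralyzable dead time, and a
  ground-truth decay ID on every single;
* prompt coincidence identification for doubles, triples and order-m
  multiples under four veto schemes — Vno, Vbetween, Vinner, Vouter —
  where a veto is a time interval that must contain no other single
  (Vouter, for example, accepts a pair only if
  `t[i]-t[i-1] > τ` and `t[i+2]-t[i+1] > τ`);
* extended delayed-window estimators of the random rates. For doubles,
  three delayed window schemes D₁, D₂, D₃ mirror each veto geometry and
  combine to the unbiased ratio estimator

  ```
  R̂ = D₁ · D₂ / D₃
  ```

  which cancels the veto-size mismatch exactly for Poisson singles. For
  two-decay random triples, a one-delay count (double {i,j} plus a single
  k in the 2τ−Δt_ij window, veto of length 2τ+span around the delayed
  single) minus a two-delay count (both gaps delayed, reproducing the
  fully uncorrelated content) gives `R̂ = D¹ᵈᵉˡᵃʸ − D²ᵈᵉˡᵃʸˢ`; for
  β⁺γ emitters the double is vetoed as well and scale schemes
  (per-single veto intervals of total length L, 2L, 3L) supply the
  correction factors
  `R̂ = (D₄¹ᵈᵉˡᵃʸ/D₃ˢᶜᵃˡᵉ² − D₄²ᵈᵉˡᵃʸˢ/D₃ˢᶜᵃˡᵉ³)·D₃ˢᶜᵃˡᵉ¹`;
  three-decay triples use two delayed windows of size τ with the halving
  rule, `R̂ = ½·D̃ˢᶜᵃˡᵉ³·(Dˢᶜᵃˡᵉ¹/Dˢᶜᵃˡᵉ³)`;
* analytic activity-dependence models `a·Aⁿ·exp(−bA)` for every scheme,
  weighted curve fitting, mean-gap statistics, and an experiment driver
  (`run_experiment()`) that sweeps activities with repetitions and
  reports every estimator's relative deviation from decay-ID ground
  truth.

## Worked example

Simulate 0.1 s of an extended ¹¹C-like source (ε₁ = 0.4, ε₂ = 0.14) at
50 MBq, then estimate the random double rate under the outer veto scheme
with τ = 2.6 ns and δ = 5 µs, and compare with the labelled truth:

```r
library(petrand)
iso <- isotope_presets()$cs_ideal_c11
s <- simulate_stream(5e7, 0.1, iso, detector_model(), seed = 42)
s
#> <singles_stream> 3402550 singles over 0.1 s (activity 5e+07 Bq, seed 42)
#>   isotope: CSideal-11C

dd  <- delayed_doubles_suite(s, 2600, "vouter", 5e6)
est <- estimate_randoms_doubles(dd$d1, dd$d2, dd$d3)
est
#> <random_estimate> doubles_vouter: 868085 /s

truth <- ground_truth_randoms(s, window_config(2600, "vouter"), "doubles")
100 * (est$estimate_rate / truth$rate - 1)
#> [1] -0.449  # percent
```

The stream holds 3.4 million singles; of the ~692k prompt doubles
accepted by Vouter, 87.2k are random, and the delayed-window ratio
estimator reproduces their rate (872,000/s) to half a percent — without
using the decay IDs. `delayed_triples_suite()` and the
`estimate_two_decay_triples_*()` / `estimate_three_decay_triples()`
functions do the same for random triples, and `run_experiment()` runs
whole activity sweeps:

```r
cfg <- experiment_config(iso, targets = c("doubles", "triples_beta"), seed = 1)
res <- run_experiment(cfg)   # 10-100 MBq, 0.1 s x 5 repetitions
res$deviations
```

A thin CLI over the same API lives at `inst/cli/petrand.R`
(`simulate | coincide | estimate | sweep | report`).

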