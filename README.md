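# fibrilslit

Single-fibril statistics and confinement simulation for kinked
nanofibrils in slits.

Cellulose nanofibrils (CNFs) traced from AFM images behave as chains of
stiff straight segments joined by sharp localized bends ("kinks"), each
kink characterized by a turning angle θ<sub>k</sub> and a bend-direction
sign s<sub>k</sub> = ±1. When such fibrils adsorb in rectangular slits of
width w comparable to their mean contour length ⟨L⟩ (weak confinement),
the adsorbed population is more aligned and more folded than the
unconfined one. `fibrilslit` provides the computational machinery to ask
whether *selectivity alone* — compact fibrils fitting between the walls
more easily — can account for the extra folding:

* a **generative population model** (`fibril_model()`): contour-length
  law, kink-count pmf (default (0.21, 0.45, 0.26, 0.05, 0.03) for 0–4
  kinks, expectation 1.24), kink-angle law, segment-partition law, and a
  nearest-neighbour Markov model of bend signs with persistence
  probability p (default 0.65);
* a **geometry-based accept/reject simulator** (`simulate_confined()`):
  fibrils are placed with uniform random orientation and transverse
  center-of-mass position in the slit 0 ≤ y ≤ w and kept only if every
  vertex fits, with the rigid-rod closed forms
  S<sub>2D</sub> = (L/3)/(πw/2 − L) and P<sub>acc</sub> = 1 − 2L/(πw)
  (for L ≤ w) as analytic cross-checks;
* the **morphology statistics** of AFM single-fibril analysis
  (`conformation_summary()`, `orientation_statistics()`,
  `detect_kinks()`, `rg_norm_sq()`): nematic order parameter
  S<sub>2D</sub> = ⟨cos 2θ⟩ with length-weighted orientation
  distributions, kink densities and segment lengths, normalized radius of
  gyration (Rg/L)², percentile bootstrap error bars, and the Onsager 2D
  excluded area 2L²/π of thin rods;
* the **bend-sign theory** (`sign_sum_theory()`): exact
  ⟨|Σ s<sub>i</sub>|⟩ = 2p, 2p²+1, 4p³−4p²+4p for 2–4 kinks (enumeration
  for more), the inversion p = (⟨s₁s₂⟩ + 1)/2, and the random-walk null
  (mean 0, variance 1).

Populations move through plain-text coordinate tables (one vertex per
row: `fibril_id, vertex_index, x_nm, y_nm`), the same layout produced by
fibril-tracing software exports, so generated and traced data share one
pipeline.

## Worked example

```r
library(fibrilslit)

# unconfined population: 65-degree kinks, <n_k> = 1.24 by construction
pop <- sample_population(fibril_model(), 5000, seed = 1)
conformation_summary(pop, kinks = "annotated")
#> <morphology_summary> 5000 fibrils
#>   <L> = 599.5 nm   <n_k> = 1.221   <theta_k> = 65.0 deg
#>   <rho_k>^-1 = 489.7 nm   <L_seg> = 327.4 nm
#>   <(Rg/L)^2> = 0.0731   S_2D = 0.3682
#>   <s1 s2> = 0.274 (p_hat = 0.637)

# slit selectivity at <L>/w = 0.80 (w = 750 nm), 70-degree proposal model
ens <- simulate_confined(
  fibril_model(kink_angle_law = list(type = "fixed", value = 70)),
  slit(750), n_accept_target = 5000, seed = 2)
ens
#> <confined_ensemble> w = 750 nm: 5000 accepted of 9561 proposed (acceptance 0.523)
conformation_summary(ens$fibrils, kinks = "annotated")
#> <morphology_summary> 5000 fibrils
#>   <L> = 598.8 nm   <n_k> = 1.296   <theta_k> = 70.0 deg
#>   <rho_k>^-1 = 461.6 nm   <L_seg> = 315.8 nm
#>   <(Rg/L)^2> = 0.0706   S_2D = 0.1611
#>   <s1 s2> = 0.357 (p_hat = 0.679)
```

Reading the numbers: the accept/reject filter raises the mean kink number
from ≈1.22 (generator, expectation 1.24) to ≈1.30 — about a 4% shift.
The accepted population is also slightly more compact (smaller (Rg/L)²)
and, because w is not much larger than L, partially aligned
(S<sub>2D</sub> ≈ 0.16 against the slit axis; an isotropic population
gives 0, the kink-free rod closed form at this ratio gives 0.346). A
purely selective slit therefore produces only a small enrichment in
folded fibrils — far below the ≈37% kink-number increase observed for
real confined fibrils, which is the argument that confinement deforms
fibrils rather than merely filtering them.

The whole comparison — unconfined vs most-confined, sign-sum theory vs
simulation, plus an upper-bound variant with equal segments and kink
angles up to 160° — runs as one reproducible pipeline:

```r
res <- run_selectivity_study(run_config(seed = 1L), out = "study_out")
res$kink_shift$relative_increase_pct   # ~4
res$upper_bound$relative_increase_pct  # ~8-9
```

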