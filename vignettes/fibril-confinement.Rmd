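---
title: "Kinked fibrils in slits: the model behind fibrilslit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinked fibrils in slits: the model behind fibrilslit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(fibrilslit)
```

## The scientific question

Cellulose nanofibrils (CNFs) traced from AFM images look like chains of
stiff straight segments joined by sharp localized bends — *kinks* — rather
than smoothly curving worm-like chains. When such fibrils adsorb inside
rectangular slits whose width $w$ is comparable to the mean contour length
$\langle L \rangle$ (weak confinement, $\langle L\rangle \sim w$), two
things are observed: the fibrils align with the slit axis, and they appear
*more folded* — more kinks per fibril, deeper kink angles, smaller radius
of gyration.

The folding observation admits two very different explanations:

1. **Selectivity**: the slit is a passive topological filter. Compact,
   kinky fibrils fit more easily between the walls, so the adsorbed
   sub-population is enriched in them even if no fibril ever changes shape.
2. **Deformation**: confinement actively changes the conformation of
   individual fibrils.

`fibrilslit` implements the quantitative machinery to test explanation 1:
a generative model of kinked fibrils, a geometry-based accept/reject
simulator of slit adsorption, and the morphology statistics needed to
compare the accepted sub-population against the unconfined one. If the
purely selective model predicts a much smaller shift than observed,
whatever remains must be attributed to deformation.

## The fibril model

A fibril is a 2D open polyline (class `fibril_chain`): vertices in nm,
interior vertices annotated as kinks. Each kink carries

* a **turning angle** $\theta_k \in (0^\circ, 180^\circ)$ — the deviation
  from straight continuation ($0^\circ$ = collinear, $180^\circ$ = complete
  fold-back). We use the turning-angle convention throughout because
  folding statements ("larger kink angles fold the fibril, lowering
  $(R_g/L)^2$") are monotone in it;
* a **bend sign** $s_k \in \{-1, +1\}$: $+1$ when the contour bends to the
  right of the direction of travel, $-1$ to the left. The sign is a
  traversal-relative quantity: reversing the tracing direction flips every
  sign while preserving every angle, which is why only reversal-invariant
  sign statistics (products, $|\sum_i s_i|$) are physically meaningful.

`build_polyline()` realizes segments/angles/signs by dead reckoning; the
heading turns clockwise at a $+1$ (right) kink. `turning_angles()` inverts
the construction exactly, and that round trip is tested to numerical
precision.

The population law (`fibril_model()`) has five pluggable parts, with
defaults emulating the unconfined CNF population the package targets:

| component | default | meaning |
|---|---|---|
| `length_law` | uniform on [550, 650] nm | contour length $L$, mean 600 nm |
| `kink_pmf` | (0.21, 0.45, 0.26, 0.05, 0.03) | $P(n_k)$ for $n_k = 0..4$; $\langle n_k\rangle = 1.24$ |
| `kink_angle_law` | fixed 65° | every kink identical; 70° for the most confined proposal model |
| `partition_law` | `"random"` | $n_k$ uniform breakpoints on $[0, L]$ (flat Dirichlet fractions) |
| `persistence_p` | 0.65 | $P(\text{same side as previous kink})$ |

Two of these deserve comment because the underlying experimental reports
leave them open:

* **"Random segment lengths"** is implemented as uniform order statistics
  (equivalently a flat Dirichlet over segment fractions). This is the
  canonical minimal-assumption reading; an `"equal"` partition is provided
  for the upper-bound variant below.
* **"Fixed kink angle"** is a point mass: every kink of every fibril gets
  exactly 65° (or 70°). A bounded-uniform law is available where only a cap
  is known.

Bend signs follow a two-state Markov chain: the first kink bends either way
with probability $\tfrac12$, each later kink agrees with its predecessor
with probability $p$ (nearest-neighbour interactions only). The default
$p = 0.65$ is the value recovered from unconfined two-kink fibrils via
$\langle s_1 s_2\rangle = p - (1 - p)$.

What the generator does *not* emulate: smooth worm-like-chain curvature
between kinks (segments are perfectly straight), fibril height/diameter,
3D effects, kink mechanics, and fibril–fibril interactions. Tests passing
on generated data therefore validate the statistical machinery and the
selective-filter logic — not any claim about the mechanics of real
cellulose.

## The confinement simulator

The slit is idealized as two parallel walls, $0 \le y \le w$, unbounded
along $x$ (experimental slits are $\sim$30× longer than a fibril, so end
effects are negligible). `simulate_confined()` repeats

1. draw a fibril from the unconfined model,
2. rotate it by a uniform angle about its arc-length centroid and place
   that centroid at a uniform transverse position in $[0, w]$
   (`place_random()`),
3. keep it iff **every vertex** satisfies $0 \le y \le w$ (`fits()`); the
   slit is convex and segments are straight, so vertex containment is
   exact whole-chain containment,

until the requested number of acceptances. The acceptance fraction and both
counts are recorded; the whole ensemble is reproducible from one seed. If
the proposal budget is exhausted before a single acceptance the simulator
raises an error rather than returning an empty ensemble — an over-tight
slit is a configuration mistake, not a statistic.

### Rigid-rod analytics

For kink-free rods the accept/reject process integrates in closed form: a
rod of length $L$ at angle $\theta$ to the slit axis fits with probability
$\max(0, w - L|\sin\theta|)/w$, giving for $L \le w$

$$ P_{\text{acc}} = 1 - \frac{2L}{\pi w}, \qquad
   S_{2D} = \langle \cos 2\theta\rangle_{\text{accepted}}
          = \frac{L/3}{\pi w/2 - L}. $$

`rod_s2d_closed_form()` / `rod_acceptance()` implement these (falling back
to quadrature for $L > w$) and serve as the analytic cross-check of the
Monte-Carlo machinery — the simulator is required, in tests, to match them
within Monte-Carlo error at each experimental ratio:

```{r rod-check}
w <- 600 / 0.80
ens <- simulate_confined(
  fibril_model(kink_pmf = 1, length_law = list(type = "fixed", value = 600)),
  slit(w), n_accept_target = 5000, seed = 42)
c(simulated = ens$acceptance_fraction, theory = rod_acceptance(600, w))
```

`s2d_weighted()` combines per-ratio $S_{2D}$ values into a population
value, weighting each $L/w$ ratio by the probability mass the contour
length distribution assigns to its bin (bin edges are midpoints between
consecutive ratios, extended outwards by half a gap). The number of ratios
and their placement are parameters, since no canonical binning exists.

## Morphology statistics

`conformation_summary()` reports, per population: $\langle L\rangle$,
$\langle n_k\rangle$, $\langle\theta_k\rangle$ (overall and per kink-count
class), the mean inverse kink density
$\langle\rho_k\rangle^{-1} = \langle n_k/L\rangle^{-1}$ (inverse of the
mean density, exactly as defined — not the mean of inverses), the mean
segment length $\langle L/(n_k+1)\rangle$, the normalized mean square
radius of gyration, $S_{2D}$ and the orientation distribution, and the
bend-sign statistics.

Numerical choices worth knowing:

* **Kink detection** (`detect_kinks()`) thresholds the turning angle at
  20° by default — the visibility limit below which a bend cannot be told
  from tracing noise. Kink-count classes with no members are reported as
  absent (`NA`/missing), never as zero.
* **Radius of gyration** (`rg_norm_sq()`) resamples the polyline at equal
  arc-length steps (default 5 nm, well below the shortest segments) so
  that mass is uniform along the contour regardless of vertex placement;
  a straight rod converges to $1/12$ as the step shrinks, and the small
  $O(1/N)$ discretization bias is tested explicitly. The point count is
  computed with a small tolerance on $L/\text{step}$ so that rigid motions
  cannot flip it across an integer boundary.
* **Orientation statistics** weight each straight segment by its arc
  length (the per-unit-contour orientation density a tracing tool would
  histogram); the director defaults to the slit axis. For isotropic
  populations this director choice cannot bias $S_{2D}$ away from 0.
* **Bootstrap** error bars (`bootstrap_ci()`) use percentile resampling
  with the fibril as the resampling unit, 1000 resamples by default.

### Sign-sum theory

For a kink-count class $n_k$, the expected net bend imbalance under the
persistence chain is, by enumeration of agreement patterns,

$$ \langle|{\textstyle\sum_i s_i}|\rangle =
   \begin{cases} 2p & n_k = 2\\ 2p^2 + 1 & n_k = 3\\
                 4p^3 - 4p^2 + 4p & n_k = 4, \end{cases} $$

with exact enumeration over $2^{n_k-1}$ patterns for any larger class
(`sign_sum_theory()`). The random-walk null $p = \tfrac12$ gives mean 0 and
variance 1 for the two-kink product; the tests require simulation and
theory to agree within three bootstrap standard errors across
$p \in \{0.3, 0.5, 0.65, 0.9\}$.

```{r theory}
vapply(2:4, sign_sum_theory, numeric(1), p = 0.65)
```

## The end-to-end selectivity study

`run_selectivity_study()` chains everything with one master seed (per-stage
substreams derived by `stage_seed()`, so stages can be re-run
independently):

1. unconfined generated population, fixed 65° kinks;
2. accept/reject at $\langle L\rangle/w = 0.80$ ($w = 750$ nm) with the
   70° proposal model;
3. sign-sum theory vs simulation table;
4. an **upper-bound variant**: equal segments and kink angles drawn
   uniformly up to 160° — the features of the most compact experimentally
   observed fibrils, giving the most generous version of the selective
   model.

All summaries mirror the image-analysis pipeline, counting kinks by
detection at the 20° visibility threshold. For the fixed-angle stages
detection and generator annotation coincide; for the 160°-capped variant
the threshold removes the shallow bends an AFM trace could not resolve
(about one kink in eight), which is what makes the variant comparable to
traced statistics. Whether the variant draws one angle per kink or one per
fibril is not determinable from the source material; we draw per kink and
verified that the per-fibril alternative changes the relative kink-number
increase by less than Monte-Carlo error.

```{r study, eval = FALSE}
res <- run_selectivity_study(run_config(seed = 1L), quiet = TRUE)
res$kink_shift    # ~1.24 -> ~1.29, a ~4% shift
res$upper_bound   # ~8-9% relative increase
```

At the sizes used for routine checking ($10^4$ fibrils per population,
$10^4$ accepted; $10^5$ in the reproduction script) the selective filter
raises the mean kink number from 1.24 to about 1.29 (≈4%), and even the
upper-bound variant only reaches ≈8–10%. Both sit far below the ≈37% shift
reported for real confined fibrils — the quantitative basis for concluding
that slits do not merely filter conformations but deform them.

## Known limitations

* Purely 2D: no out-of-plane excursions, no height profile.
* The slit filter ignores wall–fibril interaction energies and
  fibril–fibril excluded area inside the slit; `excluded_area_rod()`
  ($2L^2/\pi$ for a thin rod) only flags when the dilute-deposition
  assumption of the one-fibril-at-a-time model breaks down.
* Experimental quantities that require raw AFM images (the measured 37%
  kink increase, experimental $S_{2D}$ fits, measured length histograms)
  are out of scope; the package consumes traced coordinate tables instead.
* The generator's contour-length and segment laws are calibrated only to
  the mean contour length (≈600 nm) and the printed kink-count pmf, not to
  full experimental histograms.
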