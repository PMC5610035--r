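---
title: "Modeling the hair growth cycle as an excitable, coupled follicle field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the hair growth cycle as an excitable, coupled follicle field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haircycle)
```

## The model

`haircycle` simulates the mouse hair growth cycle as a multi-scale
activator-inhibitor system. A follicle is a one-dimensional segment of
tissue, depth 0 at the skin surface, carrying two diffusible signaling
pathways: an activator (WNT-like) and an inhibitor (BMP-like). Each pathway
has a free ligand field $L(x,t)$ and a bound ligand-receptor field
$LR(x,t)$ on the follicle axis:

$$\partial_t L = D\,\partial_x^2 L + S(x,t)
  - k_{on} L\,(R_{tot}\varphi(x) - LR) + k_{off}\,LR - \delta L,$$
$$\partial_t LR = k_{on} L\,(R_{tot}\varphi(x) - LR) - k_{off}\,LR
  - \delta\,LR + \sigma\,\varphi(x)\,\xi(t),$$

with no-flux ends. Two anatomical compartments structure the source and
receptor terms:

* **Region I (bulge)** — a fixed interval near the surface. It produces
  ligand at a small constant rate and is the only receptor-bearing
  compartment: $\varphi(x)$ is the receptor expression profile, 1 inside the
  bulge interval and falling linearly to 0 over a fixed taper on either
  side.
* **Region II (dermal papilla with hair germ or matrix)** — a fixed-width
  interval riding on the distal tip. It is the main signaling source; its
  production rate switches with the model phase (the schedule
  `production_region2`).

The read-out coupling signaling to growth is the scalar

$$C(t) = \frac{\sum_i \big(LR_{act}(x_i) - LR_{inh}(x_i)\big)}
             {\sum_i \varphi(x_i)},$$

the capacity-normalized spatial average of bound activator minus bound
inhibitor over the bulge. Two checkpoints act on $C$: a telogen follicle
enters the anagen-like phase when $C$ crosses the activation threshold
upward (the activator-amplification event of late competent telogen — the
region II activator schedule jumps to its anagen value at this moment), and
an anagen follicle enters the telogen-like phase when $C$ crosses the
termination threshold downward. The two model phases deliberately absorb
catagen and the telogen sub-states: the telogen-like phase spans catagen,
refractory and early competent telogen; the anagen-like phase spans late
competent telogen and anagen proper.

Growth closes the loop. During anagen the follicle elongates at
$v = v_{max}\,\max(C - \theta_{term}, 0) / (C_{1/2} + |C|)$ — a smooth,
saturating law that stops at the termination threshold — and during telogen
it retracts at a constant catagen speed until the resting length. The
geometry feeds back on signaling because region II moves with the tip: a
long follicle places the inhibitor source far from the bulge, a short one
places it close. This geometric feedback, not a built-in clock, is what
makes the cycle autonomous.

## Why the system cycles

In telogen the follicle is short, region II sits close to the bulge, and
the activator (high telogen production) accumulates on bound receptors
while the post-anagen inhibitor load degrades; $C$ rises toward a telogen
steady state that lies *above* the activation threshold, so telogen always
ends. Anagen entry triggers the activator production burst and growth; as
the follicle elongates, the anagen inhibitor production (delivered from an
increasingly remote region II but with a longer decay length than the
activator) accumulates in the bulge until $C$ falls through the termination
threshold. Catagen retraction then concentrates the accumulated inhibitor
into the shortening follicle — the mass-preserving re-gridding is the
mechanism — which produces the refractory telogen, and its clearance sets
most of the telogen duration.

The activation threshold deliberately sits close to the telogen steady
state of $C$. The final approach to threshold is therefore slow, which
makes late competent telogen a genuinely *poised* state: a small amount of
extra activator from a neighboring follicle advances anagen entry by days.
This is what makes the coupled system an excitable medium with clean wave
entrainment rather than a collection of stiff clocks.

## Calibrated defaults

All constants live in `hf_defaults()` and are the package's own calibration
in simulated days and arbitrary concentration units (1 time unit = 1 day;
the follicle rests at length 0.6 and grows to 2.4 with grid spacing 0.1).
The calibration was chosen once to satisfy the qualitative biology and the
package's invariants:

* the noise-free single follicle cycles indefinitely with anagen ≈ 18 d,
  telogen ≈ 58 d, period ≈ 76 d, and period variation below 0.1% after the
  first cycle;
* scaling all inhibitor sources shortens anagen and lengthens telogen
  monotonically; below ≈ 0.5x the follicle equilibrates in extended anagen,
  above ≈ 1.5x in extended telogen (the excitable window);
* elevating `receptor_total` of both pathways by 1.5x (the ventral
  parameterization: more bindable receptors make the bulge respond faster)
  shortens the period to ≈ 0.85x, so a ventral domain leads by a growing
  phase advance every cycle;
* doubling the inhibitor sources (`make_hyper_refractory`) pushes the
  telogen steady state of $C$ below the activation threshold: the follicle
  completes at most the cycle it is started in and then rests indefinitely,
  and incoming anagen waves cannot recruit it (the ear phenotype).

Tunable parameters with units, and their defaults:

| parameter | meaning | default (act / inh) |
|---|---|---|
| `diffusion_coeff` | ligand diffusion, length²/d | 0.15 / 0.15 |
| `production_region1` | constant bulge source, conc/d | 0.02 / 0.02 |
| `production_region2$telogen` | distal source in telogen, conc/d | 1.8 / 0.05 |
| `production_region2$anagen` | distal source in anagen, conc/d | 5 / 1.8 |
| `bind_on`, `bind_off` | receptor kinetics, 1/(conc·d), 1/d | 2, 0.3 / 0.5, 0.08 |
| `degradation` | ligand and complex decay, 1/d | 0.15 / 0.07 |
| `receptor_total` | bulge receptor capacity, conc | 1 / 1 |
| `activation`, `termination` | checkpoint thresholds on $C$ | 0.5, 0.08 |
| `refractory_min` | minimum phase dwell, d | 1 |
| `v_max`, `C_half`, `v_catagen` | growth law, length/d | 0.3, 0.3, 0.6 |
| `coupling_strength` | inter-follicle exchange, 1/d | scenario: 0.015–0.05 |

The slow inhibitor receptor kinetics (`bind_off` 0.08, `degradation` 0.07)
are what separate the fast activator read-out from the slow refractory
clearance; the activator anagen production burst (1.8 → 5) is the pulse
that both sharpens the follicle's own transition and recruits competent
neighbors.

## Numerical scheme and its choices

The fields are integrated with an explicit Euler scheme and the standard
central difference for diffusion, time step `dt = 0.025` d against the
stability bound $dx^2/(2D) = 0.033$ d. Choices worth knowing about:

* **Boundary Laplacian.** Both ends use the symmetric-ghost form
  $2(L_1 - L_0)/dx^2$, which makes the trapezoidal ligand mass exactly
  conserved in the closed limit (verified to 1e-10 over 10⁴ steps).
* **Moving tip.** The node count is the nearest node to the true length
  (not the floor), so the discretization error of the tip position
  oscillates around zero instead of biasing the domain short. Region II
  source weights are cell overlaps with the moving interval, normalized by
  the trapezoid cell widths so the integrated source is exactly
  `rate * width` at any resolution.
* **Receptor taper.** The receptor profile tapers linearly over a fixed
  physical margin instead of ending abruptly on a grid node, and the growth
  signal is normalized by receptor capacity. Together these remove the
  leading-order grid sensitivity: halving both `dt` and `grid_spacing`
  changes the noise-free period by < 0.1% (the package tests require
  < 2%).
* **Re-gridding.** Nodes are inserted (constant distal extrapolation) or
  removed at the tip; the ligand fields are then rescaled to the pre-step
  trapezoidal mass. On retraction this reads as catagen carrying the
  follicle's contents upward, and it is the mechanism that concentrates the
  refractory inhibitor.
* **Negative values.** Explicit stepping with additive noise can
  undershoot zero; values are clipped to 0 and counted. Ligand clips above
  1% of nodes in one step abort the run as an instability; bound-field
  clips at near-zero levels under noise are routine and only logged.
  Bound fields are also capped at the local receptor capacity.
* **Noise and reproducibility.** Stochastic increments are additive
  Gaussian on the bound fields in the bulge, scaled by
  `noise_amplitude * sqrt(dt)`, drawn from counter-based per-site streams
  (a splitmix-style finalizer with Box-Muller). A site's stream depends
  only on the master seed and the site index, never on the lattice size, so
  a fixed seed gives bit-identical trajectories and the zero-coupling
  lattice factorizes exactly into single-follicle runs.

## The population model

Lattices are 1D arrays or 2D grids with von Neumann connectivity; the
lateral (column) direction can wrap, reflecting the body's approximately
cylindrical skin. Neighboring follicles exchange free ligand of both
pathways at `coupling_strength` over the bulge depth band — the band all
follicles share regardless of their current length; the macro-environmental
pool lives near the surface. The exchange operator is symmetric, conserves
lattice-total mass to round-off, and carries no flux through barrier or
aperture sites (they are simply absent from the exchange graph).

Domains are named site sets with parameter overrides (`receptor_scale` for
ventral-like faster cycling, `inhibitor_scale` for hyper-refractory
ear-like regions, or explicit field replacements). Initial conditions seed
the first cycle: every follicle starts in late competent telogen poised
just above the activation threshold and its first anagen entry is *gated*
to its onset offset — a linear head-to-tail gradient, an optional lateral
gradient, per-domain delays, and a seeded per-site jitter (SD 1 d) that
represents developmental noise and breaks exact lattice symmetries. The
alternative `point_source` mode holds all non-source sites below threshold
with a degradable free-inhibitor reservoir, so a chosen site or row fires
first; because recruitment requires competence, a source firing into a
uniformly refractory field does not chain — sustained waves in this model
(as in skin) are a property of the ongoing rhythm, so the wave-breaking
scenarios launch an established wave from a gradient and analyze a later
cycle.

## Pattern metrics

`onset_map` extracts per-site k-th anagen entry times (cycles counted per
site from its own first entry; sites drift out of phase).
`asynchrony_persistence` is the number of leading cycles whose onset order
still follows the head-to-tail axis (Spearman rank correlation > 0.5; the
rank statistic is robust to the nonlinear compression of the gradient that
the wave entrainment produces). `bilateral_symmetry` correlates the
*row-centered* onset map with its mirror about the lattice midline. The
row-centering is deliberate and differs from a plain mirror correlation: a
purely head-to-tail gradient is itself mirror-symmetric, so the raw
statistic saturates at 1 for any front-to-back pattern and cannot
distinguish lateral symmetry from the trivial kind; after removing row
means the score measures exactly the left-right structure (1 for a
mirror-symmetric lateral pattern, about 0 for jitter, -1 for an
antisymmetric tilt). The emergence threshold 0.7 and persistence threshold
0.5 are calibration choices of this package, reported with the metric
outputs, not biological constants. `wavefront_arrival` treats an onset map
as an arrival-time field, extracts iso-arrival contours, and scores
distortion as the maximum arrival delay behind a barrier or aperture
relative to a planar front fitted on feature-free columns, converted to
site units by the fitted front speed.

## The canonical scenarios

```{r scenarios, eval = FALSE}
preset_config("single_follicle")     # autonomous cycling (period ~ 76 d)
preset_config("inhibitor_scan")      # durations vs inhibitor strength
preset_config("homogeneous_sheet")   # asynchrony persistence, 16 x 16
preset_config("two_domain")          # Ventral|Dorsal|Ventral, 16 x 20
preset_config("barrier")             # wave against a lateral barrier
preset_config("aperture")            # wave through a hole
preset_config("ear_hyper_refractory")# wave stops at a refractory domain
```

Two of them carry the package's headline quantitative behaviors, at sizes
chosen to run on a laptop in a couple of minutes each:

* **Homogeneous sheet.** A 16 x 16 grid with an 8-day head-to-tail onset
  gradient and 1-day jitter. The gradient survives as a traveling anagen
  wave: the onset-order rank correlation stays essentially 1 for the whole
  simulated horizon (14+ cycles), far longer than the 3-4 cycles over
  which real dorsal skin loses its initial ordering — replicating this
  known discrepancy is the point: a homogeneous field cannot destroy the
  initial asynchrony, and no bilateral symmetry ever emerges in it.
* **Two domains.** A central 10-column Dorsal stripe flanked by two
  5-column Ventral stripes (lateral wrap closes the cylinder), ventral
  receptor totals 1.5x, ventral onset delayed 3.5 d, dorsal head-to-tail
  gradient as above, exchange 0.015/d. The faster ventral rhythm gains
  about a quarter period per cycle; by cycle 2 its waves recruit the
  dorsal flanks symmetrically (row-centered mirror score jumps from ~0 to
  ~1 — emergence in cycle 2), and by cycle 3 the lateral recruitment has
  overwritten the head-to-tail order (rank correlation falls from ~0.67 to
  ~0.42, through the 0.5 threshold — breakdown in cycle 3, around
  simulated day 160 at these periods). These two indices are what
  `scripts/acceptance.R` recomputes.

The two-domain exchange rate (0.015/d) is smaller than the sheet's
(0.05/d): across a domain boundary the tonic ligand contrast between
dissimilar follicles is much larger than between identical ones, and
stronger exchange lets the high-receptor ventral stripe drain its dorsal
neighbors into a non-cycling state. The chosen value keeps every follicle
cycling for the simulated horizon while the ventral waves still dominate.

## What the synthetic scenarios do and do not show

The generator emulates: autonomous cycling with realistic phase structure,
initial developmental asynchrony (gradient + jitter + ventral delay),
domain heterogeneity via receptor and inhibitor levels, wave entrainment,
refractory blocking, and geometric wave-breaking. It does not emulate:
actual WNT/BMP concentrations or kinetics (all units are arbitrary),
follicle-level anatomy beyond two compartments, mechanical skin
deformation, the cellular basis of catagen, seasonal/systemic modulation,
or measurement noise of real anagen maps (pigmentation imaging). Passing
tests therefore certify the dynamical mechanism — excitability, domain
dominance, refractory blocking — not quantitative agreement with any
particular mouse.

## Known limitations

* The ventral parameterization (receptor elevation alone) shortens the
  period mostly through telogen; ventral anagen is not shorter than dorsal
  anagen in this calibration.
* The excitable window in inhibitor scaling (~0.6x to ~1.4x) is narrower
  than the plotted range of the duration-vs-strength relationship one
  might wish to explore; outside it the scan reports the non-cycling
  terminal phase instead.
* Pathway cross-talk is absent by default (`ligand-receptor binding within
  a pathway only`); the domain-override mechanism can emulate some of its
  effects but no direct coupling hook is exposed.
* With exchange on, very strong coupling (≳ 0.1/d at these kinetics)
  drives mixed-phase lattices into frozen states; the presets stay well
  below this.
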