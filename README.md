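# haircycle

Multi-scale simulation of the mouse hair growth cycle: excitable
activator–inhibitor dynamics on growing follicles, coupled into skin-wide
lattices with heterogeneous anatomical domains.

## The problem and the model

Hair follicles (HFs) regenerate cyclically — anagen (growth), catagen
(involution), telogen (rest) — and neighboring follicles coordinate through
diffusible signals, so skin behaves as an excitable regenerative field with
spontaneous anagen initiation, traveling anagen waves, fast-cycling
dominant regions, hyper-refractory regions where waves stop, and wave
distortion around anatomical obstacles. `haircycle` implements a
mechanistic model of this system for computational skin biologists: each
follicle is a moving 1D domain carrying reaction–diffusion dynamics of two
ligand–receptor pathways, an activator (WNT-like) and an inhibitor
(BMP-like):

    ∂L/∂t  = D ∂²L/∂x² + S(x,t) − k_on·L·(R_tot·φ(x) − LR) + k_off·LR − δ·L
    ∂LR/∂t = k_on·L·(R_tot·φ(x) − LR) − k_off·LR − δ·LR + noise

Ligand is produced at a constant rate in the bulge (region I, fixed, the
receptor-bearing compartment with profile φ) and at a phase-scheduled rate
in the dermal papilla compartment (region II, a fixed-width interval riding
the distal tip). The growth signal

    C(t) = Σ (LR_act − LR_inh) / Σ φ     (bulge average)

drives a saturating elongation law during anagen, constant retraction
during catagen, and the two cycle checkpoints (anagen entry when C crosses
the activation threshold upward; termination when it crosses the
termination threshold downward). Because region II moves with the tip, the
geometry feeds back on signaling and the cycle is autonomous — no built-in
clock. Lattices of follicles exchange free ligand between neighbors over
the bulge depth band; domains (ventral, hyper-refractory ear, …) are
parameter overrides on site sets; barriers and apertures are sites without
follicles or flux.

## Worked example

```r
library(haircycle)

p <- hf_defaults()                      # calibrated excitable regime
traj <- simulate_hf(p$act, p$inh, p$geometry, p$thresholds,
                    horizon = 450, dt = p$numerics$dt)
phase_durations(traj)
#>   cycle anagen telogen period
#> 1     1  21.65  58.950 80.600
#> 2     2  18.05  57.975 76.025
#> 3     3  18.05  57.975 76.025
#> 4     4  18.05  57.975 76.025
#> 5     5  18.05  57.975 76.025
```

After a one-cycle transient the follicle settles into a stable rhythm:
18.1 simulated days of anagen-like growth and 58.0 days of telogen-like
rest, period 76.0 days. Scaling all inhibitor sources shows the excitable
window and the opposing duration trends:

```r
inhibitor_strength_scan(p, levels = c(0.5, 0.7, 1, 1.2, 1.5), horizon = 420)
#>   level anagen telogen  period cycling terminal_phase
#> 1   0.5     NA      NA      NA   FALSE         anagen
#> 2   0.7 94.700  49.150 143.850    TRUE        telogen
#> 3   1.0 18.050  57.975  76.025    TRUE        telogen
#> 4   1.2 11.525  67.675  79.200    TRUE        telogen
#> 5   1.5     NA      NA      NA   FALSE        telogen
```

Stronger inhibitor signaling shortens anagen and lengthens telogen; at the
extremes cycling stops — extended anagen below, extended telogen above.

Population scenarios run from named presets:

```r
cfg <- preset_config("two_domain")      # Ventral|Dorsal|Ventral stripes
res <- run_scenario(cfg, "out/two_domain", seed = 1)
rec <- res$result
asynchrony_persistence(rec, sites = "Dorsal")      # rho: 0.93 0.67 0.42 ...
attr(bilateral_symmetry(rec, sites = "Dorsal"), "emergence")
#> [1] 2
```

The fast-cycling ventral flanks overtake the dorsal field: bilaterally
symmetric onset patterns emerge in cycle 2, and the built-in head-to-tail
asynchrony of the dorsal domain breaks down in cycle 3 (rank correlation
0.67 → 0.42 across the 0.5 threshold). On a homogeneous sheet
(`preset_config("homogeneous_sheet")`) the same initial asynchrony instead
persists as a traveling wave for 14+ cycles and no symmetry ever emerges —
heterogeneous domains are required for rapid pattern evolution.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/haircycle simulate-skin --preset two_domain --seed 1 --out out/
```

## Package tour

* `pathway_params()`, `hf_geometry()`, `phase_thresholds()`,
  `default_growth_law()`, `hf_defaults()` — model specification.
* `reaction_diffusion_step()`, `growth_signal()`, `geometry_step()`,
  `checkpoint_update()` — single-follicle operations.
* `simulate_hf()`, `phase_durations()`, `inhibitor_strength_scan()` —
  single-follicle simulation and analysis.
* `build_lattice()`, `domain_spec()`, `make_hyper_refractory()`,
  `initial_conditions()`, `coupling_step()`, `simulate_population()` —
  the population model.
* `onset_map()`, `asynchrony_persistence()`, `bilateral_symmetry()`,
  `wavefront_arrival()` — spatiotemporal pattern metrics.
* `load_config()`, `save_config()`, `preset_config()`, `run_scenario()`,
  `write_record()` — JSON configuration and reproducible bundles.

The methods vignette (`vignettes/haircycle-methods.Rmd`) documents the
model, the numerical scheme, the calibration and its limitations.
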