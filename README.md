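# woundfield

Reaction–diffusion modelling of the bistable JNK/AP-1 – JAK/STAT
signalling field that forms around a wound in *Drosophila* wing imaginal
discs.

After localized damage, the disc epithelium splits into a wound-proximal
high-JNK/AP-1 domain and a surrounding high-JAK/STAT domain.  A central
question is whether the one-way repression of JNK by JAK/STAT suffices to
explain this spatial separation, or whether the pathways must repress
each other (**mutual repression**, the classic toggle-switch motif, here
embedded in space).  `woundfield` answers it the way the modelling
literature does: simulate both network topologies to steady state over a
large log-uniform ensemble of parameter sets, classify every steady state
as bistable or not, and compare.

The model: four dimensionless species on the center-to-periphery axis
$x \in [0,1]$, discretized into 100 compartments (method of lines),

$$\partial_t E = \gamma\big(\mathbb{1}(x) - E + k_{act,E}\,H_{n_1}(J;K_E)\big) + \nabla^2 E,$$

$$\partial_t J = \gamma\Big(1 - k_{deg,J}J + \frac{k_{act,J} H_{n_2}(E;K_J)}{1 + k_{inh,J}^{ni_1} S^{ni_1}}\Big),\qquad
\partial_t S = \gamma\Big(1 - k_{deg,S}S + \frac{k_{act,S}\,U\,H_{n_3}(S;K_S)}{1 + k_{inh,S}^{ni_2} J^{ni_2}}\Big),$$

$$\partial_t U = \gamma\big(1 - k_{deg,U}U + k_{act,U}\,H_{n_4}(J;K_U)\big) + d\,\nabla^2 U,$$

with $H_n(u;K) = u^n/(K^n + u^n)$ and the red mutual-repression factor
$(1 + k_{inh,S}^{ni_2} J^{ni_2})$ present only in the mutual topology.
$E$ (Eiger/TNF-α) and $U$ (Upd cytokines) diffuse; the wound is the
basal-Eiger region $x \in [0, 0.05]$.  Steady states are reached by a
stiff banded implicit integrator (LAPACK banded LU, Newton-quenched
steady states) with an independent damped-Newton root-finding oracle.

Bistable patterns are classified two ways: **simple** (JAK rises, JNK
falls, both endpoint relative differences strictly > 10%) and
**observed** (Pearson r > 0.7 against reference reporter profiles for
both gradients).  The package also provides the reporter-profile
pipeline (track aggregation, max-scaling, LOESS smoothing with span
0.8) and a synthetic-data module that generates noisy reporter tracks,
reference profile pairs, and an analytically labelled classifier fixture
battery, so everything runs without external data.

## Worked example

One mutual-repression parameter set drawn from the scan (seed 1,
set 1280), integrated to steady state:

```r
library(woundfield)
cfg <- model_config(topology = "mutual")
rec <- run_scan(sampling_config(n_sets = 2000, seed = 1), model_config())
p   <- attr(rec, "params")
q   <- dimensionless_params(as.list(p[p$set_id == 1280, param_names()]))

ss <- integrate_to_steady_state(q, cfg)
ss
#> wound-field steady state (mutual topology): converged at t = 0.02173,
#>   max|du/dt| = 3.92e-09
round(ss$state$JNK[c(1, 100)], 3)   # wound vs periphery
#> [1] 58.700  0.341
round(ss$state$JAK[c(1, 100)], 3)
#> [1]  0.025 36.200
classify_simple(ss)$simple
#> [1] TRUE
```

JNK is ~170-fold higher at the wound than at the periphery and JAK is
~1,400-fold higher at the periphery: a sharp bistable field.  The
half-max position of the JNK gradient (0.0489) nearly coincides with the
JNK–JAK intersection point (0.0496) — the interface.  Rerunning the
*same* parameter set without the JNK→JAK repression term collapses the
pattern:

```r
cfg$topology <- "unidirectional"
ssu <- integrate_to_steady_state(q, cfg)
round(ssu$state$JAK[c(1, 100)], 3)
#> [1] 36.2 36.2        # JAK spatially flat: no bistability
classify_simple(ssu)$simple
#> [1] FALSE
```

At ensemble scale the asymmetry is drastic.  On the 2,000-set paired scan
above:

```r
compare_models(rec)$summary[, c("topology", "n_observed", "n_simple")]
#>         topology n_observed n_simple
#> 1         mutual        338        6
#> 2 unidirectional          0        0
```

The mutual-repression model produces hundreds of solutions matching the
experimentally observed gradient shapes; the unidirectional model
produces none.

## Command line

```sh
inst/cli/woundfield scan --n 1000 --seed 1 --topology both --out results/scan
inst/cli/woundfield compare  --records results/scan/records.csv --out summary.csv
inst/cli/woundfield density  --records results/scan/records.csv --parameter kact_JNK --out dens.csv
inst/cli/woundfield make-tracks --seed 5 --out tracks.csv
```

Every seeded command is byte-reproducible; each scan directory carries a
`manifest.json` with config, seeds, timings and file digests.

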