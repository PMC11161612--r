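# quorumsim

Quorum sensing (QS) is the cell–cell communication mechanism by which
bacteria switch on collective gene programs — biofilm formation,
virulence, bioluminescence — once the concentration of a secreted
signal molecule (an *autoinducer*) crosses a critical threshold.
`quorumsim` is an R package for microbiologists and modellers who want
a quick, scriptable answer to the question *"will this colony sense
quorum, and if not, how thick does the biofilm have to get?"* before
committing to wet-lab work.

## The model

Each cell is a Gaussian point source of width `Ws` releasing
autoinducer at rate `P` (molecules·cell⁻¹·s⁻¹) into a medium with
diffusion coefficient `D`. The steady-state field of one cell is

    N(r) = P / (2 π D r) · φ( r / (√2 Ws) ),

with `φ` the error function, so the far field decays as `P/(2πDr)` and
the origin value is finite, `P / (√2 π^{3/2} D Ws)`. For a spherical
colony of radius `R` with uniform cell density `n`, superposing the
shells gives the centre concentration

    N_total = (P n R² / 2D) · [ 1 − (Ws²/R²) φ(R/(√2 Ws))
                                + √( (2Ws/πR) · e^{−(R/2Ws)²} ) ],

which the package also evaluates by direct adaptive quadrature of the
underlying integral `(P n / D) ∫₀ᴿ r φ(r/(√2 Ws)) dr` as an
independent check. QS is declared when `N_threshold ≤ N_total`; because
`N_total` is strictly increasing in `R`, the minimum biofilm thickness
that triggers QS is the unique root of `N_total(R) = N_threshold`,
solved by bisection.

A Monod chemostat model supplies time dynamics: substrate `θ` and cell
density `β` evolve as

    dθ/dt = (θ_in − θ) α − μ(θ) β / γ,
    dβ/dt = (μ(θ) − α − k_dec) β,      μ(θ) = μ_max θ / (K_s + θ),

and `β(t)` replaces `n` in the colony formula (optionally with the
colony radius growing as `R₀ (β/β₀)^{1/3}`) to produce the
time-dependent autoinducer curve across the lag, log, stationary and
death phases.

## Worked example

```r
library(quorumsim)

# the anchor colony: P = 5000 molecules/cell/s, n = 1e6 cells/mL,
# R = 0.45 mm, D = 1e-6 cm^2/s, Ws = 1 um
p <- colony_parameters(5000, 1e6, 0.45, 1e-6)
to_nanomolar(colony_concentration_closed_form(p))
#> 8.406438 nM

# calibrate the threshold so this colony is exactly critical, then ask
# how thick the biofilm must be in a faster medium
thr <- calibrate_threshold(p)
minimum_thickness(colony_parameters(5000, 1e6, 0.45, 3e-6), thr)
#> [1] 0.7794216   (mm; attributes record 36 bisection steps, ~1e-8 nM residual)

run_scenario("fig2b_minthickness")
#>   param value N_total_nM feasible  R_min_mm
#> 1     D 1e-06   8.406438     TRUE 0.4500000
#> 2     D 2e-06   4.203219    FALSE 0.6363953
#> 3     D 3e-06   2.802146    FALSE 0.7794216
#> 4     D 4e-06   2.101609    FALSE 0.8999983
#> 5     D 5e-06   1.681288    FALSE 1.0062286
```

Reading: at the calibrated ~8.41 nM threshold a 0.45 mm biofilm senses
quorum when `D` = 1e-6 cm²/s, but as the medium gets faster the signal
is carried away and the minimum thickness climbs with √D, reaching
about 1 mm at `D` = 5e-6 cm²/s.

The same operations are available from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","quorumsim.R",package="quorumsim"))')" \
  minthickness --production_rate 5000 --cell_density 1e6 --diffusion 3e-6 \
  --threshold_nM calibrated
# R_min = 0.779 mm
```

with subcommands `feasibility`, `minthickness`, `sweep`, `growth`,
`couple` and `scenarios`, flat `key = value` config files, CSV output
and optional plots (exit codes: 0 success, 2 input error, 3 bracket
failure, 4 integrator failure).

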