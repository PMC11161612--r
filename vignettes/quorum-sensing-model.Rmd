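---
title: "The quorumsim model: diffusion-limited autoinducer accumulation and Monod growth coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The quorumsim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quorumsim)
```

## The physical picture

A bacterium secreting a small signalling molecule at a constant rate is,
on colony length scales, a point source smeared over the cell body. We
model the source as an isotropic Gaussian of width $W_s$ (the bacterial
cell width, about 1 µm) releasing $P$ molecules per second into a medium
with diffusion coefficient $D$. At steady state the concentration field
of a single cell is

$$N(r) = \frac{P}{2\pi D r}\,\phi\!\left(\frac{r}{\sqrt{2}W_s}\right),
\qquad \phi(x) = \frac{2}{\sqrt{\pi}}\int_0^x e^{-h^2}\,dh ,$$

where $\phi$ is the error function. Far from the cell
($r \gg W_s$) the profile saturates and the field is the familiar
point-source form $P/(2\pi D r)$; near the origin the error function's
linear behaviour cancels the $1/r$ divergence, leaving the finite centre
value

$$N(0) = \frac{P}{\sqrt{2}\,\pi^{3/2} D W_s}.$$

A Taylor-approximation prefactor $(2\pi)^{-3/2}$ is sometimes quoted for
this limit; it is exactly half the continuity-consistent value above.
`single_cell_origin()` exposes both conventions, but the field returned
by `single_cell_concentration()` always uses the series limit — a
discontinuous field would break the root-finding that the feasibility
layer depends on. The switch to the limiting value happens at
$r < 10^{-6} W_s$, far below any physically meaningful radius, and the
field is continuous there to better than $10^{-9}$ relative.

## The colony concentration

A spherical colony of radius $R$ with uniform cell density $n$ is the
continuum superposition of these sources. Evaluated at the colony
centre, the spherical-shell integral is

$$N_{total} = \frac{P n}{D}\int_0^R r\,
  \phi\!\left(\frac{r}{\sqrt{2}W_s}\right) dr ,$$

with the closed-form (Taylor-refined) evaluation

$$N_{total} = \frac{P n R^2}{2D}\left[1
  - \frac{W_s^2}{R^2}\,\phi\!\left(\frac{R}{\sqrt{2}W_s}\right)
  + \sqrt{\frac{2W_s}{\pi R}\,e^{-(R/2W_s)^2}}\right].$$

The bracket is written exactly as stated, exponential inside the square
root with exponent $(R/2W_s)^2$; for every realistic colony
($R/W_s \gtrsim 30$) that last term underflows to zero, so the stated
grouping is numerically inert and is kept purely for fidelity.
`colony_concentration_quadrature()` evaluates the integral directly by
adaptive quadrature (relative tolerance $10^{-10}$, hard subdivision
cap, estimated error reported) and serves as the independent oracle: the
two routes agree to better than $10^{-3}$ relative for $R/W_s > 300$ and
$10^{-2}$ down to $R/W_s = 50$, which is also what the test suite
asserts over randomized parameter sets. Below $R/W_s = 10$ the closed
form warns that the wide-colony approximation is degrading.

Two structural facts about the closed form drive everything downstream:
$N_{total}$ depends on $P$ and $n$ only through the product $Pn$
(linearity), and its leading behaviour is $P n R^2/2D$ — quadratic in
the colony radius, inverse in the diffusion coefficient.

## Units

Internally everything is CGS: cm, seconds, molecules. The user-facing
constructors accept the units practitioners quote — colony radius in mm,
cell width in µm, density in cells/mL, thresholds in nM — and convert
once at the boundary; concentrations are tagged objects
(`qs_concentration`) so a molecules-per-cm³ value cannot be silently
compared against a molarity. The nM conversion is
$\text{nM} = \text{molecules·cm}^{-3} \times 10^{12}/N_A$ with
$N_A = 6.02214076 \times 10^{23}$.

## Feasibility, calibration and minimum thickness

Quorum sensing is declared when $N_{threshold} \le N_{total}$ — a
non-strict comparison, so a colony exactly at threshold is sensing. The
threshold itself is organism- and reporter-dependent; the package
default is 10 nM as a round literature-scale value, but the documented
path to self-consistent numbers is `calibrate_threshold()`: pick a
reference colony known (or assumed) to be exactly critical and use its
$N_{total}$ as the threshold. The packaged reference is
$P = 5000$ molecules·cell⁻¹·s⁻¹, $n = 10^6$ cells/mL, $W_s = 1$ µm,
$D = 10^{-6}$ cm²/s and $R = 0.45$ mm, which calibrates to
$\approx 8.41$ nM.

```{r}
thr <- calibrate_threshold(reference_colony())
thr
```

Because $N_{total}(R)$ is strictly increasing, the minimum biofilm
thickness that triggers QS is the unique root of
$N_{total}(R) = N_{threshold}$. `minimum_thickness()` solves it by
bisection — deliberately so: the function is cheap and monotone, and
bisection converges unconditionally, which matters more here than the
few extra iterations a derivative-based method would save. The default
bracket spans one cell width to 100 mm and the solver tightens to
$10^{-9}$ mm, leaving a threshold residual far below $10^{-6}$ relative;
both endpoints are checked first and a failure names the side that does
not straddle the root.

```{r}
run_scenario("fig2b_minthickness")
```

The $\sqrt{D}$ structure of this table follows from the leading term:
at fixed threshold, $R_{min} \propto \sqrt{D}$, so doubling the
diffusion coefficient multiplies the critical thickness by $\sqrt{2}$
to within the sub-percent correction contributed by the bracket.

## Growth dynamics

Time dependence enters through a single-species chemostat: substrate
$\theta$ (gCOD/mL) flows in at dilution rate $\alpha$ and is consumed by
cells $\beta$ (cells/mL) that grow by the Monod law and decay at a
first-order rate $k_{dec}$:

$$\frac{d\theta}{dt} = (\theta_{in} - \theta)\,\alpha
  - \frac{\mu(\theta)\,\beta}{\gamma},
\qquad
\frac{d\beta}{dt} = \bigl(\mu(\theta) - \alpha - k_{dec}\bigr)\,\beta,
\qquad
\mu(\theta) = \frac{\mu_{max}\theta}{K_s + \theta}.$$

The yield $\gamma$ (cells per gCOD) links consumption to growth; writing
the consumption term as $\mu\beta/\gamma$ is what makes the batch
invariant exact: with $\alpha = k_{dec} = 0$,
$d(\beta + \gamma\theta)/dt = 0$, and the test suite holds the
integration to that identity at $10^{-6}$ relative over 240 h. The same
form makes the washout criterion literal — whenever
$\mu_{max} < \alpha + k_{dec}$ no substrate level can sustain the
culture and $\beta \to 0$; with $\mu_{max} = 0$ the decay is exactly
$\beta_0 e^{-(\alpha + k_{dec})t}$, one of the closed forms the suite
checks. (An equivalent formulation multiplies the growth term by the
yield and reads $\mu$ as a specific uptake rate; we state the model in
the growth-rate convention because that is what $\mu_{max}$ in 1/h
means.)

Integration uses deSolve's `lsoda` (stiff-capable, adaptive) at relative
tolerance $10^{-8}$; the reporting grid is decoupled from the internal
steps, so output CSVs are reproducible regardless of step-size
adaptation. State is never clipped inside the integrator — only the
reported values and the Monod-rate argument are floored at zero, to keep
round-off excursions from turning into NaNs.

### Default scenario

The packaged batch scenario is $\theta_{in} = \theta_0 = 5\times10^{-3}$
gCOD/mL, $\beta_0 = 10^4$ cells/mL, $\alpha = 0$, $\gamma = 10^9$
cells/gCOD, $k_{dec} = 0.01$ h⁻¹, $\mu_{max} = 0.3$ h⁻¹ and
$K_s = 55.2$ on a $10^{-4}$ gCOD/mL scale, simulated for 240 h at 0.5 h
reporting. These values were chosen once as a realistic bench-scale
batch culture whose four growth phases all fall inside the 240 h
window: the culture idles briefly, grows exponentially to a peak of
$\approx \gamma\theta_{in} = 5\times10^6$ cells/mL near 60 h as the
substrate exhausts, and then declines at the decay rate. The
half-saturation constant is a dimensionless-looking number in most
summaries of this model; we treat it in the same units as $\theta$, and
the packaged pair (55.2 vs 17, `fig3_ks_pair`) is expressed on the
$10^{-4}$ scale so both values are commensurate with the default
substrate level. Lower $K_s$ means faster growth at the same substrate,
so the 17 culture leads the 55.2 culture throughout the growth phase.

## Coupling growth to the signal

`couple_autoinducer()` substitutes $\beta(t)$ for the static density $n$
at every reported time, holding per-cell production $P$ constant. Two
modes isolate the one genuinely open modelling choice:

* **density_only** — the colony radius stays at $R_0$;
  $N_{total}(t) \propto \beta(t)$ exactly.
* **density_and_radius** (default) — the sphere enclosing the cells
  grows with the population at fixed packing density,
  $R(t) = R_0(\beta(t)/\beta_0)^{1/3}$, the minimal assumption that ties
  radius to cell number; with the bracket near 1 this makes
  $N_{total} \propto \beta^{5/3}$.

In both modes the instantaneous concentration is a monotone function of
$\beta$, so the autoinducer maximum can never precede the population
maximum: the signal peaks at the onset of the death phase and then
declines with the active-cell count. The packaged `fig2f_growth`
scenario uses $R_0 = 0.45$ mm at the inoculum; since the comparative
curves are normalized by their maxima (`normalize_series()`, which
divides by the maximum and passes all-zero series through unchanged),
$R_0$ only rescales the raw curve.

```{r}
cpl <- run_scenario("fig2f_growth")
c(peak_cells_h = cpl$time_h[which.max(cpl$cells)],
  peak_signal_h = cpl$time_h[which.max(cpl$N_total_nM)])
```

## Numerical choices and degenerate inputs

* Bisection tolerance $10^{-9}$ mm (about 60 iterations worst case over
  the default bracket); the returned root carries the iteration count
  and threshold residual as attributes.
* Quadrature: `stats::integrate`, relative tolerance $10^{-10}$,
  500-subdivision cap; non-convergence is an error carrying the
  estimated absolute error, never a silent approximation.
* $R = 0$ is a valid quadrature input (empty colony, zero
  concentration); the closed form requires $R \ge W_s$ because a colony
  narrower than one cell is not a colony.
* An empty culture ($\beta_0 = 0$) couples to an all-zero, all-valid
  autoinducer series, not an error.
* The pipeline contains no randomness anywhere; identical inputs give
  bit-identical CSVs.

## Scope and limitations

The model is a steady-state, single-species, spatially homogeneous
idealisation. The concentration is evaluated only at the colony centre —
the most favourable point — so feasibility verdicts are optimistic for
cells at the rim. Autoinducer degradation, binding, advection and
spatially structured biofilms are outside the model, as are co-culture
dynamics. The growth coupling holds per-cell production constant across
phases, whereas real cells modulate secretion; the packaged scenarios
therefore demonstrate the transport-and-population arithmetic of quorum
sensing, not the gene regulation layered on top of it. Passing tests
show internal consistency of this idealisation against independent
numerics and closed forms — they do not by themselves validate the model
against any particular organism.
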