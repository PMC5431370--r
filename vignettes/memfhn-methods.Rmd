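---
title: "Methods: the memristive FitzHugh-Nagumo media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the memristive FitzHugh-Nagumo media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`memfhn` simulates a two-dimensional excitable media of FitzHugh-Nagumo
type in which electromagnetic induction acts on the membrane potential.
Each node carries three variables: the membrane potential $u$, the slow
recovery current $v$, and the magnetic flux $\varphi$ across the membrane,
all dimensionless:

$$
\begin{aligned}
\partial_t u &= -k\,u(u-a)(u-1) - uv + k_0\,\rho(\varphi)\,u
  + D_u \nabla^2 u,\\
\partial_t v &= \Big(\varepsilon + \frac{\mu_1 v}{u+\mu_2}\Big)
  \big({-v} - k\,u(u-a-1)\big),\\
\partial_t \varphi &= k_1 u - k_2 \varphi + F(x, y, t),
\end{aligned}
$$

with the flux-controlled memductance $\rho(\varphi) = \alpha +
3\beta\varphi^2$ — the derivative of a memristor's cubic charge-flux
constitutive relation. The cubic term plus $-uv$ is the aggregate
trans-membrane ionic current; the feedback $k_0\rho(\varphi)u$ is the
faradic current induced by flux variation, which is how the tissue's own
electromagnetic field (and any external radiation) modulates excitation.
A `baseline` mode drops the feedback and restores the classical
two-variable kinetics with an external stimulus current $I_{st}$ instead;
the three-variable `induction` mode carries no $I_{st}$ term (and every
canonical experiment sets $I_{st}=0$ anyway).

Model assumptions worth keeping in mind: the tissue is homogeneous and
isotropic (one parameter set everywhere, scalar diffusion on $u$ only),
the lattice is square with no-flux edges (no current leaves the tissue),
and the flux equation is linear in $\varphi$ apart from the memductance
coupling back into $u$.

### Parameters

All parameters are dimensionless. Defaults (`model_params()`):

| parameter | default | meaning |
|---|---|---|
| `k` | 8 | cubic-nonlinearity gain |
| `a` | 0.15 | excitation threshold |
| `eps` | 0.002 | recovery time-scale separation |
| `mu1`, `mu2` | 0.2, 0.3 | recovery-rate shape; the rate divides by `u + mu2` |
| `I_st` | 0 | stimulus current (baseline mode only) |
| `D_u` | 1 | diffusion coefficient of `u` |
| `k0` | 0.1 | induction feedback gain |
| `k1` | 0.5 | flux-drive gain |
| `k2` | 1 | flux-leak gain |
| `alpha`, `beta` | 1, 2 | memductance offset and curvature |

`k0 = 0.1` (the default) is the regime in which the stripe seed develops
a stable spiral; larger `k0` (0.4, 0.9) magnetizes the media toward
homogeneity. Small `k2` (0.15) destabilizes the flux and breaks the
spiral seeds; large `k2` (3.0) yields a standing spiral.

## Numerics

**Integrator.** Explicit Euler forward with time step `h = 0.03`
throughout, matching the scheme the model family is studied with;
higher-order or adaptive integrators are deliberately out of scope (step
halving is used only to verify the first-order error scaling in the
tests). All three fields update synchronously from the state at time
$t$.

**Grid and spacing.** 200 x 200 nodes over a physical square of side
350, so the node spacing is `dx = 350/200 = 1.75`, and the five-point
Laplacian divides by `dx^2`. That is the literal reading of the stated
geometry; because many excitable-media codes instead treat the lattice
spacing as 1, `grid_spec(unit_spacing = TRUE)` exposes that variant. The
shipped presets and the acceptance checks all use the literal
`dx = 1.75`; the qualitative regimes (spiral/suppressed/broken/standing)
reproduce under it.

**Boundary.** No-flux via mirror ghost nodes: the neighbour beyond an
edge carries the edge value itself, the simplest scheme with an exactly
vanishing normal gradient. It makes the diffusion stencil conservative:
with the reaction disabled (the `mode = "diffusion"` test hook) the
lattice sum of `u` is conserved to round-off, which the tests assert at
relative 1e-10 over 1000 steps.

**Initial conditions.** The spiral-nucleating stripe seed places three
six-row bands across columns 1-115 of the 200-grid — `(u, v, phi)` =
`(1, 0, 0)`, `(0.7, 0.6, 0.1)`, `(0, 0.8, 0.2)` on rows 92-97, 98-103,
104-109 — on a rest background. Ranges are read as 1-based inclusive
`(row, column)` slices, stored internally as 0-based offsets; rows first
is the chosen convention (the figures cannot disambiguate it), and the
resulting left-half wedge does break the front and curl a spiral. On
other grid sizes the band indices rescale proportionally.

**Snapshot timing.** Requested snapshot times map to the nearest integer
step (`h = 0.03` divides neither 10 nor 200 exactly); the realized time
is attached to each snapshot.

**Degenerate inputs and failure policy.** The recovery rate is undefined
on the line `u = -mu2`; evaluation within a configurable guard band
(default 1e-12) raises an error rather than clamping, so NaN can never
propagate silently. Divergence (any |state| beyond a configurable bound,
default 1e6) likewise aborts with the failing time attached — states are
never clipped. A bifurcation scan catches per-value failures, flags
them, and continues the scan.

**Determinism.** Deterministic runs are bit-for-bit reproducible.
Stochastic forcing draws one standard normal per in-disk node per step,
in fixed (patch order, then column-major) order, from R's RNG — so
`set.seed()`/`seed =` makes whole simulations reproducible bit-for-bit,
and a checkpointed run continues bit-identically to an uninterrupted one
when the RNG stream position is preserved.

## External forcing

Both drives act on the flux equation only.

**Radiation** is the static profile $A e^{-m r}$ around a center
$(x_0, y_0)$; default `A = 12`, `m = 0.06`, center (84, 84). Although
written $F(x, y, t)$, the profile has no stated time dependence and is
implemented as static (and cached). Centers and radii are in node-index
units by default — centers like (84, 84) or (60, 60) and radius 40 sit
naturally in the 200 x 200 index space — with a `units = "physical"`
switch.

**Noise** is Gaussian white noise of intensity `D` (default 9) confined
to a disk (default radius 40 at (60, 60); `radius = Inf` covers the
media). The continuous-time convention behind the default `em`
discretization is $\langle\xi(t)\xi(t')\rangle = 2D\,\delta(t-t')$,
giving per-step increments of standard deviation $\sqrt{2Dh}$
(Euler-Maruyama). A `naive` mode adds increments of standard deviation
$hD$ instead, a pattern common in older excitable-media codes. The
original update rule for this model family is not recoverable, so both
conventions are first-class.

**Why the noise presets use `naive`.** At the canonical conditions
(`D = 9`, `h = 0.03`, `k2 = 1.6`) the `em` convention is numerically
explosive: the flux reaches excursions of $|\varphi| \sim 5$-$7$
(stationary sd $\sqrt{D/k_2} \approx 2.4$), the memductance feedback
$k_0(1 + 6\varphi^2)u$ then exceeds the explicit-Euler stability limit
of the cubic kinetics at `h = 0.03`, and the run diverges within a few
dozen steps. Bounded turbulent activity out to $t = 800$ under this
noise is only attainable with the `naive` scaling, so the noise presets
(`fig12`, `fig14`) and the reproduction script use `naive`; `em` remains
the default of `noise_increment()` itself, with a documented warning.
This is a property of the discretization at this step size, not of the
model.

## Measurement instruments

**Peaks.** A sample is a peak only if it strictly exceeds both adjacent
samples; plateaus and endpoints never count. Bifurcation scans discard a
transient before detection — by default the first half of the run, a
recorded configuration field, since the diagrams are meant to show
asymptotic amplitudes. The full peak set per parameter value is stored,
so either diagram style (all peak values, or only the maximum) is
derivable.

**Activity labels.** `classify_activity()` is a pure function of the
peak set, the series and explicit thresholds: quiescent below an
amplitude floor of 0.05 (or at most one peak); periodic when inter-peak
intervals and peak values both have relative dispersion below 5%;
multimodal when the peak values split at a sorted-value gap exceeding 3x
the within-cluster spread; irregular otherwise. All three thresholds are
arguments.

**Phase and singularities.** The model itself defines no phase, so the
phase instrument is an addition of this package, in the standard
excitable-media style: per-node angle $\operatorname{atan2}(v - v_0,
u - u_0)$ around a reference inside the oscillation loop. The default
reference is the post-transient $(u, v)$ centroid of the monitored
node's trajectory (an oscillating node's centroid lies inside the loop);
it is configurable, and `pattern_metrics()` records the reference used.
Singularities are plaquettes whose wrapped phase differences wind by
$\pm 2\pi$; charges are signed so that a field
$\operatorname{atan2}(col - c_0, row - r_0)$ carries charge +1.

One honest caveat: in the strongly irregular small-`k2` regime
(`k2 = 0.15`) the field develops structure at the grid scale (node-to-
node jumps of order 1), and the singularity count saturates in the
thousands. There it should be read as a turbulence index — "very many
phase defects" — not as a census of discrete spiral cores; the
qualitative comparisons only use its ordering against the 1-2 cores of
the standing-spiral regime.

**Pattern classes.** `classify_pattern()` maps (spatial std of `u`,
core count) to `suppressed` (< 0.05), `spiral` (1-3 cores), `broken`
(> 3), else `patterned`; both thresholds are arguments.

## What the generated data does and does not emulate

All inputs are synthetic: the stripe seed, homogeneous states, and the
forcing recipes are the study conditions themselves, so tests exercise
exactly the conditions of interest. The generator reproduces an
idealized, homogeneous, isotropic, noiseless-measurement tissue. It does
**not** emulate real cardiac data: no fiber anisotropy or spatial
heterogeneity, no electrode/measurement noise, no physiological ion-
channel detail, no physical units. Passing tests therefore certify the
model's documented dynamics and the instruments' correctness on known
ground truth — not any claim about real cardiac pathology.

## Verification design and problem sizes

Every operation is checked against an independent oracle: literal
transcriptions of the kinetics evaluated by expression parsing, naive
double-loop Laplacian and per-node step references, closed-form linear-
ODE relaxation with step-halving, constructed phase fields of known
topological charge, and exhaustive peak scans. The compiled lattice
kernel must agree with the pure-R `media_step()` path and the naive loop
to 1e-12 per node.

The qualitative reproductions run at the full canonical size (200 x 200,
t = 200, or t = 800 for the noise-robustness protocol with five noise
seeds); one t = 200 run takes a few seconds in the compiled kernel, and
the complete acceptance check a couple of minutes on one CPU. Unit tests
of the scan/preset plumbing use proportionally scaled-down grids
(16-64 nodes per side), where the stripe seed rescales to the same
geometry.

## Known limitations

- Explicit Euler at `h = 0.03` is close to the stability edge in the
  strong-feedback regimes; the package aborts on divergence rather than
  stabilizing the scheme, by design.
- Rectangular isotropic tissue only; no heterogeneous parameters,
  operator splitting or implicit solvers.
- Phase-singularity counting needs a sensible reference point; for a
  fully quiescent media the centroid reference is meaningless (the count
  is reported but the spatial standard deviation is the meaningful
  measure there).
- No spiral-tip trajectory tracking, Lyapunov estimation or frequency-
  domain turbulence measures.
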