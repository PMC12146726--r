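---
title: "Reversible molecular simulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversible molecular simulation: methods and design}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(revsim)
```

# The problem

Fitting a classical force field to condensed-phase experimental data means
computing `dl/dsigma_j`: the derivative of a loss `l` — measured on a
molecular dynamics trajectory — with respect to the force-field parameters
`sigma_j`. Differentiating through the integrator with reverse-mode automatic
differentiation gives exact gradients but stores every intermediate state
(memory linear in trajectory length) and runs several times slower than the
simulation itself. revsim implements the alternative: run the simulation
*backwards in time*, replaying the thermostat noise from stored integer
seeds, and accumulate the gradient explicitly with a small set of per-atom
vectors. Memory is effectively constant in the number of steps and the
arithmetic per reverse step is comparable to a forward step.

# The integrator and its inverse

The forward step is the Langevin middle scheme (velocities offset half a
step from positions; `E = exp(-gamma dt)`, `n_i` Gaussian with the Boltzmann
velocity scale `sqrt(kB T / m)`):

    v' = v + dt f/m
    x' = x + (dt/2) v'
    v_new = E v' + sqrt(1 - E^2) n_i
    x_new = x' + (dt/2) v_new

`gamma = 0` reduces it to leapfrog Verlet. Because the noise is regenerated
from per-step integer seeds (`noise_ledger()`), the step has an algebraic
inverse; the thermostat line inverts with `exp(+gamma dt)`. (A typeset
version of this inverse circulates with `exp(-gamma dt)` in the velocity
line; that form does not undo the forward thermostat update, and the
implementation is pinned instead by the test that `reverse_step()` composed
with `forward_step()` is the identity to 1e-12.) The inverse is exact in
exact arithmetic but not bitwise in floating point, so the forward pass
stores full `(x, v)` checkpoints every 1 ps (configurable) and the reverse
pass resets to them, bounding the drift; on the 64-atom Lennard-Jones
fixture a 1 ps reverse segment retraces the trajectory to better than
1e-6 nm and the checkpoint-reset walk matches the forward snapshots to
1e-9 nm.

# The accumulation recursion

For a loss `l(x_n, v_{n-1/2}, sigma)` seeded with `gx = dl/dx_n` and
`gv = dl/dv_{n-1/2}`, the package carries per-atom vectors

    A_i = (1 + E) dl/dx_i + (2/dt) E dl/dv_{i-1/2}
    B_i = A_i - A_{i+1}

with the update, per reverse step into `i - 1`:

    u            = (da_{i-1}/dx)^T A_i          (coordinate-side contraction)
    (dl/dsigma) += (dt^2/2) A_i^T (da_{i-1}/dsigma)  (parameter-side)
    B_{i-1}      = E B_i + (1 + E)(dt^2/2) u
    A_{i-1}      = A_i + B_{i-1}

where `a = F/m`. The dl/df carriers exposed as `C` and `D` in the
`accumulation_state` are the one-step-shifted pair `C_{i-1} = A_i`,
`D_{i-1} = B_i`; the physical force derivative at each step is
`dl/df_{i-1} = (dt^2 / 2m) C_{i-1}`. The recursion was derived by applying
the chain rule to one integrator step and closing the recursion in
`(dl/dx, dl/dv)`; several printed renderings of the initialisers are
typographically ambiguous (fraction and `dt`-power placement), so every
coefficient was frozen against the unrolled-simulation oracle below. The
derivation reproduces the known closed forms for the first two reverse steps
and the free-particle coefficient series: in units of `dt^2/(2m)` the
coefficient multiplying the coordinate seed grows as 1.999, 3.996, 5.991,
7.984 for `gamma = 1 ps^-1, dt = 1 fs`, and exactly 2, 4, 6, 8 for
`gamma = 0`. That near-arithmetic growth is gradient explosion: it motivates
**gradient truncation**, the default being 200 reverse steps per loss
snapshot. Truncation is preferred over norm clipping (more accurate
gradients); an explosion guard aborts with a diagnostic if an accumulator
grows by 1e12 over its seed. With snapshots every 2000 steps and a 200-step
window the reverse pass walks exactly 10% of the trajectory
(`truncated_window_schedule()`), skipping dead stretches by reloading stored
snapshots.

Losses that couple several time points (the mean-squared-displacement
diffusion estimator) emit one seed per contributing frame; each seed gets an
independent accumulation state and independent truncation, and the total
gradient is the sum of per-seed contributions plus the explicit
`dl/dsigma` terms. Losses defined as averages over K snapshots scale their
seeds by 1/K, which realises the snapshot-averaged chain rule.

# The two contractions

Each reverse step needs two vector-Jacobian contractions of the force
function: `d/dx (w . a)` and `d/dsigma (w . a)`. For conservative forces the
coordinate contraction equals the directional derivative of `F` along
`w/m`, and both are evaluated through the *same* pair-loop kernel used for
the forward forces, by complex-step perturbation (step 1e-100): exact to
machine precision, no automatic-differentiation framework, and no separate
derivative code to keep in sync. The neighbour list is treated as a constant
structure inside these contractions; that is exact because list membership
is a superset of the interacting set and pair terms are masked at the
cutoff.

Two independent oracles check every gradient path:

* `unrolled_chain_rule_gradient()` propagates dense sensitivities
  `dx/dsigma, dv/dsigma` through the literally unrolled integrator, using
  analytic pair Hessians (`V'`, `V''`, `d2V/dr dparam` hand-derived for all
  four pair forms — a disjoint code path from the complex-step kernel). On
  every tiny test system the reversible gradient agrees with it to 1e-10
  relative, the desk-scale analogue of gradients "numerically identical" to
  differentiating the forward simulation.
* `finite_difference_gradient()` re-runs the whole simulate-then-loss
  pipeline with common random numbers; agreement to 1e-6 relative.

The dense oracle excludes angle terms (their third-order geometry derivative
is not worth hand-deriving for an oracle); angle forces and their
contractions are covered by the finite-difference route instead.

# Potentials and systems

Four non-charge nonbonded forms share the pair kernel: Lennard-Jones
(TIP3P-oxygen starting values sigma 0.315 nm, epsilon 0.636 kJ/mol), the
double exponential (alpha 16.766, beta 4.427, minimum `-epsilon` at
`2^(1/6) sigma`), the Buckingham form `A exp(-Br) - C r^-6` (starting values
fitted to the LJ curve, see below), and the Lennard-Jones soft core with
`r_sc = (r^6 + alpha sigma^6 lambda^2)^(1/6)` (`p = 2`), finite at `r = 0`
and exactly LJ when `alpha lambda = 0`. Hydrogens carry no non-charge
nonbonded term. Electrostatics use the Tironi reaction field with solvent
dielectric 78.5 (configurable; the published setup names the approximation
but not its constants), shifted to zero at the cutoff, no self-term.
Pair interactions are plainly truncated at the 1 nm cutoff (no switching
function), which leaves a small force discontinuity there; tests keep the
cutoff well beyond the structured part of g(r). Unlike pairs mix by
Lorentz-Berthelot, and geometric/arithmetic means on energy-like/length-like
parameters for the other forms (the source material is silent on mixing;
these are the field's defaults and are isolated in one function). Bonds and
angles are harmonic with the TIP3P starting values (O-H 0.09572 nm,
462750 kJ mol^-1 nm^-2, H-O-H 1.824 rad, 836.8 kJ/mol); all intramolecular
nonbonded pairs are excluded (the conventional rigid-molecule choice; the
source does not state its exclusion rule). Near-collinear angles
regularise the torque factor to zero below `sin(theta) = 1e-10` rather than
dividing by it.

The Buckingham starting parameters (A = 359999 kJ/mol, B = 37.795 nm^-1,
C = 0.002343 kJ mol^-1 nm^6) are reproduced by `fit_buckingham_to_lj()`:
relative-error least squares against the TIP3P LJ curve on r in
[0.30, 0.70] nm. The fitting protocol behind the published values is not
described; this one recovers all three within 5% and is frozen as the
package's definition.

Everything runs in MD units (kJ/mol, nm, ps, K, g/mol;
kB = 0.0083144626 kJ mol^-1 K^-1), in double precision throughout — single
precision visibly degrades the forward/reverse identity. Positions are kept
unwrapped during integration (wrapping is not invertible and the MSD needs
continuous coordinates); `wrapped_positions()` gives the in-box copy.

# Losses

* **Enthalpy of vapourisation**: `H_vap = U_gas - (U_liq + 2.8)/n + RT`
  against the experimental 44.12 kJ/mol as a squared error averaged over
  snapshots. The +2.8 kJ/mol compensates simulating flexible water while
  reference models constrain bonds; the gas term is precomputed once and
  treated as constant, so seeds flow only through the liquid energy.
* **RDF match**: a differentiable radial distribution function — each pair
  distance deposits a Gaussian kernel (default width 0.01 nm on a 0.01 nm
  grid) normalised by the ideal-gas shell density, so a uniform fluid gives
  g of 1 — compared by the sum of absolute differences (subgradient 0 at
  ties). The published differentiable-RDF procedure is cited without
  constants; kernel width and grid are exposed in the API.
* **Diffusion coefficient**: Einstein relation over the tagged gas
  molecules' centre-of-mass MSD, averaged over all time origins with
  segments spanning half the trajectory, `D = MSD/(6 t)`; 1 nm^2/ps =
  1e-6 m^2/s, pinned by a hand-converted unit test. The squared deviation
  from 2.0e-9 m^2/s is scaled by 1e18, and water losses enter a combined
  loss with weight 0.05, matching the published weighting.

# Ensemble-reweighting baseline

`reweighting_gradient()` implements the ForceBalance-style fluctuation
formula `d<O>/dsigma = <dO/dsigma> - beta (<O dE/dsigma> - <O><dE/dsigma>)`
in its local (zero-perturbation) form, with analytic `dU/dsigma` per frame;
no MBAR across states. It is the standard route for time-independent
observables and the comparison baseline for the reversible gradients: on
the harmonic oscillator it reproduces `d<x^2>/dk = -kB T / k^2` within
Monte-Carlo error, and across a 3 x 3 grid of (sigma, epsilon) parameter
sets on the LJ fluid the two methods' RDF-loss gradients rank-correlate
above 0.8. Both methods consume the same number of snapshots.

# Training loop

`run_training()` mirrors the published protocol at desk scale: per epoch,
build or perturb the system, equilibrate, run production with snapshots,
compute the gradient by the chosen method, divide parameters by their
starting values (so differently-sized parameters take comparable steps),
clip each normalised gradient component at 1000, and apply one Adam update
(learning rate 2e-3 for water-scale problems in the published setup; the
toy recoveries below use larger rates suited to their few-minute budgets).
An epoch whose simulation goes unstable is skipped with the parameters
unchanged and a logged diagnostic. No barostat is used anywhere: gradients
through Monte-Carlo volume moves are ill-defined, so the box is fixed at
the target density (the published training also drops the barostat for
production, keeping it only in equilibration — a step this package omits
entirely). Training is bit-reproducible under fixed seeds in
single-threaded R.

# What the synthetic generators emulate, and problem sizes

The generators define the study conditions. `generate_water_box()` defaults
to the full training condition (895 TIP3P-geometry waters in a 3 nm cube,
2685 atoms, 295.15 K); `generate_gas_in_water()` to 10 O2 in 885 waters
(2675 atoms), gas molecules tagged for the MSD. Tests exercise the same
code on smaller boxes (27 waters, 1.6 nm) with proportionally smaller
cutoffs. The toy fluid is 64 argon-mass atoms at reduced density 0.5 —
small enough that the whole gradient test suite runs in minutes on one CPU.
Initial configurations are jittered lattices with Boltzmann velocities:
they reach a liquid-like steady state within the few-ps epoch
equilibration, but they are not pre-equilibrated bulk water, and no
long-range electrostatics beyond the reaction field are included — passing
tests demonstrate the correctness of gradients and the training machinery,
not the condensed-phase accuracy of any fitted parameter set.

Parameter-recovery experiments are posed so the answer is known by
construction:

* *RDF recovery*: the reference curve is generated at epsilon 0.8 under the
  same epoch protocol as training (same equilibration, duration and
  snapshot cadence, averaged over six replicas) using the same Gaussian
  kernel estimator as the loss. Matching the estimator matters: against a
  hard-binned reference the loss minimum is displaced above the generating
  epsilon, because training compensates the kernel's peak smoothing by
  deepening the well. With the matched reference the minimum sits at the
  generating value and training from 0.5 recovers epsilon within 10% in 60
  epochs.
* *Harmonic recovery*: the loss `(<(x - x0)^2> - kB T / k*)^2` on a noisy
  mean sits above the true k by about `Var(mean)/mean^2`, so the fixture is
  an ensemble of 10 independent tethered oscillators with `gamma = 2 ps^-1`
  to decorrelate snapshots; that puts the statistical bias near 3% and the
  trained k (averaged over the last 20 epochs) within 10% of the
  generating value from a 2x mis-initialisation.

# Numerical choices and limitations

* Neighbour lists rebuild every 10 steps with a 0.15 nm default skin and
  require `cutoff + skin < min(box)/2` (minimum image).
* Tie-breaks: the absolute-value subgradient at zero is 0; the minimum-image
  convention takes the half-open interval `[-box/2, box/2)`.
* Degenerate inputs error early and name the offender: overlapping atoms in
  non-soft-core forms, wrapped coordinates fed to the MSD, seeds off the
  snapshot grid, zero starting values for trainable parameters.
* Orthorhombic boxes only; no constraints, virtual sites, Ewald/PME, tail
  corrections or barostats; triclinic cells and BAOAB-type splittings are
  out of scope. The MSD estimator assumes the diffusive regime (a ballistic
  trajectory returns `v^2 t/6` by construction, which the tests document).
* The complex-step contractions cost one complex force evaluation per
  reverse step plus one per trainable parameter; for the handful of
  parameters of molecular-mechanics models this keeps the reverse pass
  within a small factor of the forward pass, and the truncation schedule
  reduces the walked fraction further.
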