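---
title: "A lattice quorum-sensing model with a resistor-network bioluminescence readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lattice quorum-sensing model with a resistor-network bioluminescence readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxnet)
```

## The model

`luxnet` simulates a growing bacterial colony as a stochastic cellular
automaton on an $L \times L$ square lattice and reads its collective state
out as an electrical current.  The target system is *Vibrio harveyi*, whose
quorum sensing (QS) runs on three autoinducers (HAI-1, AI-2, CAI-1) detected
in parallel, and whose bioluminescence is the classic indirect observable of
QS.  The package has three layers:

1. **Colony dynamics.**  Each occupied site carries a positive integer
   *c-charge* $Q$, a fictitious charge standing for the cell's current
   gene-regulation effectiveness.  Charges interact through a long-range
   Coulomb-like potential
   $$V(r') = \sum_{r \ne r'} \frac{Q(r)}{|r - r'|},$$
   summed over the whole grid with Euclidean distances in lattice units and
   the self-term excluded.  The per-site energy is $e(r) = Q(r)V(r)$, and
   half the site sum (each pair is counted twice) is the pairwise
   interaction energy $\beta^{-1}$ that plays the role of a temperature.
   Autoinducer exchange between neighboring cells is mimicked by directed
   *channels*: every alive cell may open a channel to each alive neighbor at
   strictly lower potential, with Boltzmann-like probability
   $\min(1, e^{-\beta(e_{\mathrm{donor}} - e_{\mathrm{receiver}})})$.
   A receiver touched by $k$ channels then grows by
   $\lfloor \sigma k / N \rfloor$ charge units, with $N = L^2$ and
   $1 < \sigma < N$ an activation efficiency.  Finally the colony evolves
   spatially: a cell reaching $Q_{\max}$ dies (its site empties), a cell
   with $Q \ge Q_{\mathrm{rep}} = 2$ and an empty neighbor colonises the
   empty neighbor of lowest potential with $\lfloor Q/2 \rfloor$ of its
   charge, and a cell with $Q = 1$ migrates to the empty neighbor of lowest
   potential.  Cells act in random order within the step; charge is created
   only by the update rule and destroyed only by death.

2. **Resistor-network readout.**  At every iteration the lattice is read as
   a random resistor network between two ideal contacts (the first and last
   rows, held at unit potential difference).  A channel between sites $n, m$
   carries resistance
   $$R(n,m) = D(n,m)\,[\rho_{\min} h + \rho_{\max}(1-h)], \qquad
     h = \frac{W^{\gamma}}{g^{\gamma} + W^{\gamma}},$$
   where $D$ is the channel length (1 or $\sqrt 2$), $W$ is the two-step
   average of the endpoint charges,
   $W = \tfrac14[Q_n(t) + Q_m(t)] + \tfrac14[Q_n(t-1) + Q_m(t-1)]$, $g$ is
   the half-response charge and $\gamma$ the Hill number.  The total current
   at stationarity, averaged over the post-onset segment, is the
   *bioluminescence analogue* $BA(\gamma)$.

3. **Bioluminescence mapping.**  Light output follows the phenomenological
   power law $BL = k\,BA^{\alpha}$ with $\alpha = 3$, and the Hill number of
   a strain is the *additive* combination $\gamma = \sum_{i \in S}\gamma_i$
   of per-autoinducer cooperative weights over the autoinducers $S$ the
   strain expresses.  Mutant panels are therefore points on one simulated
   $BA(\gamma)$ curve, and `fit_bl_model()` recovers the weights from
   observed relative light levels by constrained least squares.

## Parameters and calibrated defaults

| parameter | meaning | default | units |
|---|---|---|---|
| `grid_side` | lattice side $L$ | 50 | sites |
| `initial_fill` | inoculation density | 0.05 | fraction of sites |
| `q_max` | death threshold / lifetime scale | 80 | charge units |
| `q_rep` | reproduction threshold | 2 | charge units |
| `sigma` | activation efficiency | $N/2$ | — |
| `eq3_norm` | update normalisation $N$ | $L^2$ | sites |
| `hill_g` | half-response charge $g$ | 0.7 | charge units |
| `hill_gamma` | Hill number $\gamma$ | 5 | — |
| `rho_min`, `rho_max` | resistivity bounds | 1, 1000 | arb. units |

Two parameters of the model have no published value and were fixed by a
one-time calibration, after which they are ordinary package defaults:

* **$\sigma = N/2$.**  The update increment $\lfloor \sigma k/N\rfloor$
  depends on $\sigma$ only through $\sigma/N$; with $\sigma = N/2$ a
  receiver gains $\lfloor k/2 \rfloor$ units for $k$ incident channels.
  This is the simplest choice that (a) lets the 5 % inoculum bootstrap
  (small asymmetric clusters already produce receivers with $k \ge 2$) and
  (b) caps the growth rate of interior cells at a constant (at most 4
  units/step under the Moore neighborhood) *independent of $Q_{\max}$*, so
  the death–rebirth cycle time is proportional to $Q_{\max}$.  That
  proportionality is what produces the observed $\sim Q_{\max}^{-0.9}$
  falloff of the collective oscillation frequency.
* **$g = 0.7$.**  $g$ positions the sigmoidal $BA(\gamma)$ curve.  It was
  calibrated once by scanning $g \in [0.5, 30]$ on three fixed seeds and
  comparing the six two-component-mutant light reductions implied by the
  published cooperative weights against their published values; $g = 0.7$
  reproduces all six within a few percentage points, and the result is
  stable across seeds.  Small $g$ means a channel responds as soon as its
  endpoints hold roughly one charge unit, i.e. the readout discriminates
  *occupied* network structure rather than charge magnitude — consistent
  with $BA$ depending only weakly on $Q_{\max}$.

## Design choices where the model description is open

* **Eq.-3 normalisation and channel counting.**  The charge-update rule
  counts the channels *incident* to a receiver (its directly connected
  sites).  On a lattice this count is at most 8, so meaningful increments
  require $\sigma$ of order $N$; $\sigma$ is kept configurable with the
  invariant $1 < \sigma < N$.
* **Receivers are alive.**  Channels open between cells; empty sites join
  the colony only through the reproduction transfer (the $0 \to mQ$ birth
  transition).  This keeps the conservation accounting exact: reproduction
  and migration conserve charge, only death destroys it, only the update
  rule creates it.
* **Neighborhood.**  "Nearest neighbors" is taken as the 8-connected Moore
  neighborhood (diagonal channels have length $\sqrt 2$), which favors the
  rounded colony fronts seen in real biofilm images; a 4-connected option
  is provided.
* **Odd charges.**  Colonisation transfers $\lfloor Q/2 \rfloor$ and keeps
  the remainder, so integer charge is conserved exactly.
* **Scheduling and ties.**  Within the evolution phase, cells act in a
  fresh random permutation each step (asynchronous update, no raster
  artifacts); ties for "lowest potential" are broken uniformly at random
  from the run's stream.  A site that died this step cannot be recolonised
  in the same step.
* **Background edges.**  Where no channel opened, the neighbor pair still
  carries the maximal resistance $D\rho_{\max}$.  The linear system is
  therefore never singular, and with $\rho_{\max}/\rho_{\min} = 1000$ the
  unopened paths contribute only a small current floor (this floor, not
  zero, is the dead-lattice current).
* **Contacts.**  "One side to the other" is realised as the full first and
  last rows acting as equipotential bus bars.
* **Hill memory.**  The two-step average $W$ uses the charges at the
  charge-update point of the current and of the previous iteration,
  matching the phase order (update → readout → evolution).  Channels
  themselves are rebuilt every iteration; the memory lives in $W$ only.
* **Stationarity rule.**  The onset of the asymptotic regime is the first
  step at which the total charge reaches 90 % of its trailing-half mean;
  traces whose crossing lands in the final 10 % of the run are rejected as
  non-stationary.  `onset_time()`, `asymptotic_ba()` and
  `oscillation_frequency()` share this single rule.
* **Randomness.**  Each run consumes one `set.seed(config$seed)` stream in
  a fixed order (links, then evolution order and tie-breaks, per step).
  Multi-run drivers such as `ba_curve()` derive consecutive per-run seeds
  from the base seed.  Identical configurations give byte-identical traces.

## Numerical notes

* The long-range potential is a dense matrix–vector product against a
  precomputed inverse-distance kernel ($2500^2$ entries at $L = 50$),
  cached per grid size.
* The Kirchhoff system is solved by a sparse Cholesky factorisation of the
  interior-node conductance Laplacian; the symbolic analysis is cached
  across steps because the lattice sparsity pattern never changes.  Every
  solve is verified against the node-law residual at a relative tolerance
  of $10^{-8}$.
* $BA(\gamma)$ exploits the fact that the colony dynamics do not depend on
  the readout: one run is read out at the whole $\gamma$ grid, at the cost
  of one extra linear solve per $\gamma$ per step.
* The weight fit is a log-parameterised BFGS least squares (positivity by
  construction) with a quadratic barrier keeping every strain's
  $\gamma$-sum inside the simulated curve's range; the curve itself is
  interpolated by a monotone piecewise-cubic spline and never extrapolated.
* Standard errors: across seeds for $BA(\gamma)$ curves; batch means within
  a run (8 batches) for a single run's $BA$, since the stationary current
  oscillates and naive errors would be optimistic.  Reduction uncertainties
  are first-order (delta-method) propagations.

## Problem sizes used by the tests and the reproduction script

Simulation-backed checks run the published geometry (a $50\times50$ grid,
5 % inoculation): the $Q_{\max}$ sweep uses $Q_{\max} \in \{20,40,80,160\}$
with 5 seeds each and $150 + Q_{\max}$ iterations per run, and the
$BA(\gamma)$ curve uses $Q_{\max} = 80$, 5 seeds, and 26 $\gamma$ values
spanning $[0.3, 2.35]$ over 150 iterations.  These lengths leave roughly a
hundred stationary iterations after the onset (which sits near step 40 at
$Q_{\max} = 80$), enough for several death–rebirth cycles at every
$Q_{\max}$ used.

## What the simulator does and does not emulate

The generator reproduces the *collective phenomenology* of a QS colony: a
stationary total charge that scales linearly with $Q_{\max}$, collective
oscillations from synchronised death–rebirth cohorts whose frequency falls
off as a power of $Q_{\max}$, circular-front colony growth, and a sigmoidal
$BA(\gamma)$ readout.  It contains no nutrient fields, no explicit
autoinducer diffusion–reaction chemistry, no luciferase photochemistry and
no substrate mechanics; autoinducers enter only through the channels, the
Hill weights and the power-law light mapping.  Passing tests therefore
certify the model's internal laws and its mapping to the published mutant
panels — not a mechanistic prediction for real colonies.

## Known limitations

* The additive ("democratic") combination of cooperative weights is an
  ansatz; with relative panels only, $k$ is not identifiable and $\alpha$
  must be fixed (the published shared value is 3.0) unless absolute light
  data are supplied.
* The frequency estimate is limited to one spectral bin of the stationary
  segment; short runs at large $Q_{\max}$ (few cycles) carry visibly
  coarser frequency resolution.
* The printed two-component reductions near 99 % sit deep in the saturated
  tail of the cube law, where relative BA errors triple; reductions there
  are reliable, but *recovering* weights from such panels is
  ill-conditioned (the published caveat that the nonlinear fit "may have no
  real solution" applies).
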