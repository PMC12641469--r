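---
title: "Decoupling atoms through the neighbor list: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoupling atoms through the neighbor list: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlalchemy)
```

## The method

Any cutoff-based potential — classical or machine-learned — evaluates
energies from a neighbor list: the pairs $i,j$ with minimum-image distance
$d_{ij} < r_\mathrm{cut}$, with $d_{ij}$ tabulated for the potential's use.
This package performs alchemical transformations entirely at that level.
An atom **masked** from the list is invisible to the potential, exactly as
if deleted. A pair selected for **decoupling** has its tabulated distance
replaced by a $\lambda$-dependent shifted distance $d^{(k)}(\lambda)$,
$k \in \{1,2,3,4\}$:

$$
\begin{aligned}
d^{(1)} &= d + \lambda r_\mathrm{cut} &
d^{(2)} &= d + \lambda\max(0, r_\mathrm{cut}-d) + \lambda\varepsilon\\
d^{(3)} &= \sqrt{d^2 + (\lambda r_\mathrm{cut})^2} &
d^{(4)} &= \sqrt{d^2 + \lambda\max(r_\mathrm{cut}^2-d^2,\,0)} + \lambda\varepsilon
\end{aligned}
$$

Schemes 1 and 2 are linear offsets; 3 and 4 are Euclidean norms of a
4-vector whose fictitious fourth component grows with $\lambda$. Schemes 1
and 3 push pairs *beyond* the cutoff at $\lambda = 1$; schemes 2 and 4
land them *on* the cutoff sphere, clearing it by an $\varepsilon$-order
excess. All four satisfy $d^{(k)}(0) = d$ exactly, $d^{(k)}(1) \ge
r_\mathrm{cut}$, and monotonicity in $\lambda$, so the selected
interactions switch off smoothly with no end-point catastrophe: a solvent
atom sitting on top of a nearly decoupled solute atom still has a large
*shifted* distance and a finite, small energy.

Three consequences define the implementation:

* Pairs whose shifted distance reaches $r_\mathrm{cut}$ are dropped from
  the list rather than retained with a long distance. For any potential
  that vanishes continuously at the cutoff (ours does, by construction)
  this is exact.
* Forces on the real coordinates acquire a chain factor
  $\partial d^{(k)}/\partial d$ per modified pair; the fictitious fourth
  dimension exerts no force. The factor is 1 for scheme 1, $1-\lambda$ for
  scheme 2, and $d/d^{(3)}$ resp. $d(1-\lambda)/\!\sqrt{d^2 +
  \lambda(r_\mathrm{cut}^2 - d^2)}$ for the 4D schemes (with limit 0 at
  $d = 0$, $\lambda > 0$ — the shift is stationary there, which is also
  what keeps the decoupled end state regular).
* Only solute–solvent cross pairs are modified for absolute solvation
  free energies; intrasolute and solvent–solvent pairs pass through
  untouched. A per-atom selector (vanishing atom: effective
  $\lambda_\mathrm{eff} = \lambda$; appearing atom:
  $\lambda_\mathrm{eff} = 1 - \lambda$; the two never interact) drives the
  dual-topology relative transformation.

### The $\varepsilon$ guard

Written with a bare $+\varepsilon$, schemes 2 and 4 would violate the
$\lambda = 0$ identity by a rounding-guard amount. This package scales the
guard as $\lambda\varepsilon$: identity at $\lambda = 0$ is then exact
while $\lambda = 1$ still clears the cutoff by at least $\varepsilon$.
Default $\varepsilon = 10^{-4}$ Å, generous for single precision and
irrelevant in double. Whether production codes use the bare or scaled
form is an open choice; the scaled form is the only one satisfying both
stated end-state properties simultaneously, which is why it is the
package default.

## The toy potential

A trained network is not needed to validate the machinery, because the
method never touches the potential. The stand-in is a Lennard-Jones pair
term with Lorentz–Berthelot combining, multiplied by a cubic switch from
$0.8\,r_\mathrm{cut}$ to $r_\mathrm{cut}$, making energy and first
derivative continuous and exactly zero at the cutoff — the property that
makes dropped pairs exact. Default species: solvent `W`
($\varepsilon_s = 0.2$ kcal/mol, $\sigma = 3.0$ Å, 18 amu — a
water-oxygen-scale particle), solute core `S` (0.3, 3.2, 16), variant `V`
(0.15, 2.5, 2 — a small hydrogen-like particle), ghost `G`
($\varepsilon_s = 0$). $r_\mathrm{cut} = 5$ Å. A contract for real
potential backends (energy strictly from a supplied pair list with
overridden distances) is part of the design; only the pairwise case is
verified numerically here, and for genuinely many-body potentials the
shifted distance would enter higher-order features whose behavior this
package cannot probe.

## Sampling

Windows are sampled with BAOAB-discretized Langevin dynamics at 300 K.
Defaults: timestep 1 fs (retry path: 0.5 fs), friction 1 ps$^{-1}$ for
generic use and 2 ps$^{-1}$ in the free-energy protocols (faster
thermalization of the small boxes), NVT. Units: Å, kcal/mol, amu, ps.
Velocities are drawn from Maxwell–Boltzmann per window; windows inherit
their starting configuration from the previous $\lambda$ window after a
per-repeat pre-equilibration (default 1000 steps) at the first state.
A window that goes non-finite — or whose velocities exceed $10^4$ Å/ps, a
blow-up detector far above any physical speed here — is retried once from
the start with the timestep halved and the saving interval doubled, so
physical length and frame count are preserved; persistent instability is
an error naming the window and atom. An isotropic Monte Carlo barostat is
provided for NPT but deliberately not used in the validation protocols:
the checks here (scheme equivalence, cycle closure) are state-point
independent, and NVT removes barostat noise.

## Estimation

Saved frames are subsampled by a fixed rule: discard the first 20%
(window-specific equilibration), keep every fourth of the remainder. No
autocorrelation analysis is layered on top; this mirrors the fixed
production recipe and is a deliberate fidelity choice. Retained samples
are re-evaluated at neighboring $\lambda$ states and each window pair is
estimated with BAR, solved by bisection of Bennett's self-consistent
equation to a residual below $10^{-10}$, then summed over windows. The
headline uncertainty is the sample standard deviation over independent
repeats (default 3), not the BAR asymptotic error, which is nevertheless
reported per window.

MBAR is implemented as a *diagnostic*, not the production path. Samples
from near-decoupled states can place solvent atoms inside the solute;
re-evaluated at coupled states these configurations can show absurdly low
energies and attract disproportionate weight, corrupting the multistate
solution. `mbar_with_diagnostics()` flags every sample whose re-evaluated
reduced energy at a distant state lies more than 50 $k_BT$ (an internal
default; any figure well beyond physical fluctuations serves) below that
state's own sampled minimum, and reports each flagged sample's share of
the cross-state weight at the affected state. Because a converged MBAR
weight is capped at $1/N$ per state, "dominating" is meaningful — and
diagnostic — relative to the other cross-state samples. Non-convergence
returns the report instead of failing; window-wise BAR remains the
default throughout.

## Protocols and the validation logic

`run_asfe()` decouples the solute in solution over a $\lambda$ schedule
(production preset: the 15-value set $\{i/19\}$,
$i \in \{0..9, 11, 13, 15, 17, 19\}$, denser near the coupled end) and
reports $\Delta G_\mathrm{solv} = -\Delta G_\mathrm{decouple}$. The gas
leg of that thermodynamic cycle is *identically* zero because intrasolute
pairs are never modified — and this is verified numerically at every
$\lambda$, not assumed. `run_rsfe_analog()` transforms variant T1 into T2
with both variant atoms present (dual topology), each held near its site
by a flat-bottom restraint (zero inside $r_0$, harmonic outside);
identical restraint definitions at both end states are asserted so their
dummy-state contributions cancel.

Correctness is then checked without any external reference: the relative
solvation free energy difference computed via the two absolute legs must
equal the one computed via the two relative legs,
$$\mathrm{closure} = \Delta G_\mathrm{gas} + \Delta G_\mathrm{solv}(T2)
- \Delta G_\mathrm{aq} - \Delta G_\mathrm{solv}(T1) \approx 0$$
with a root-sum-of-squares propagated error.

One construction detail matters for exactness: all four legs of a cycle
must share the *same* solvent particle set, placed in the same frame.
`run_toy_cycle()` therefore solvates the dual (union) topology once,
reuses the surviving solvent for every leg, and anchors every leg at the
shared solute-core centroid. With per-leg independent solvation the legs
would differ in solvent count by a few particles and closure would carry a
systematic term of several tenths of a kcal/mol — a lesson this package's
own development confirmed numerically.

## The synthetic systems

Everything runs from seeded generators; a clean offline checkout
reproduces every number. The toy solvent box is 50 `W` particles in a
12 Å cube (the box must exceed $2 r_\mathrm{cut}$), placed uniformly and
relaxed by steepest descent until no pair is closer than $0.85\sigma$.
The toy solute is a rigid 3-particle `S` core (each atom flat-bottom
restrained to its site, $k_f = 25$ kcal/mol/Å², $r_0 = 0.25$ Å) plus one
`V` variant particle restrained ($k_f = 10$, $r_0 = 0.5$ Å) at one of two
sites at different distances from the core, so the two end states
genuinely differ — a toy analog of a tautomer pair. These values were
chosen once for a liquid-like reduced density ($\rho\sigma^3 \approx
0.8$), stable 1 fs dynamics, and end states separated by a few tenths of
a kcal/mol; none is tuned per experiment.

What the toy data do *not* emulate: electrostatics and long-range
interactions, molecular flexibility and constraints, many-body potential
terms, real water structure, NPT production. Passing tests therefore
demonstrate the correctness of the alchemical machinery — list algebra,
masking/deletion equivalence, force chain rule, estimator behavior, cycle
closure — not the physical accuracy of any particular potential.

## Numerical choices

* Double precision throughout; a `single_precision` switch on the toy
  potential rounds per-pair distances and energies through IEEE single,
  for studying guard-distance behavior.
* Neighbor lists are rebuilt every step (no Verlet skin): correctness
  first; desk-scale systems make the $O(N^2)$ rebuild cheap, and the hot
  loop is compiled.
* The kink of $\max(\cdot, 0)$ at $d = r_\mathrm{cut}$ never arises:
  shifted pairs are restricted to $d < r_\mathrm{cut}$ by construction.
* BAR bisection brackets by doubling, 200 iterations max; MBAR
  self-consistent iteration, tolerance $10^{-8}$ on reduced free
  energies, 2000 iterations, log-sum-exp throughout.
* Overlapping *unmodified* pairs ($d < 10^{-6}$ Å) are a hard error in
  force evaluation; *modified* pairs at $d \to 0$ are regular (their
  chain factor vanishes for the 4D schemes) and are skipped in the force
  accumulation with zero contribution.

## Problem sizes used in the shipped validation

The shipped test suite runs windows of 3000 steps (3 ps) saved every 10
steps, 15-window schedules for the scheme-equivalence study and 11-window
uniform schedules with 3 repeats for the 20-seed cycle-closure study —
sizes chosen so the entire validation runs on one desk CPU in well under
half an hour while leaving every statistical check at 3-standard-error
resolution. The per-window BAR uncertainties at these sizes are a few
hundredths of a kcal/mol; repeat standard deviations of full ASFE legs
are 0.2–1.5 kcal/mol, consistent with what a force-field protocol of
similar length would give.

## Known limitations

* Orthorhombic boxes only; no constraints, virtual sites, or triclinic
  cells.
* The relative-transformation protocol is an *analog*: single-atom
  appear/disappear with restraints, not a general multi-atom topology
  map; transforming larger groups would need masking and decoupling
  combined.
* Only pairwise potentials are exercised numerically; the architecture
  independence claim for many-body networks rests on the list contract,
  not on a worked many-body example.
* The $\lambda$ schedule is exposed as configuration; no claim of
  optimality is made for any preset, and the best schedule depends on how
  the offset is scheduled.
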