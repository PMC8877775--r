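---
title: "Cluster-based statistical thermodynamics with qce: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based statistical thermodynamics with qce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qce)
```

## The model

Quantum cluster equilibrium (QCE) theory describes an associated fluid as a
mixture of molecular clusters $C_p$ ($p = 1, \dots, N$, sizes $i_p$) in
chemical equilibrium with the monomer,

$$ i_p\, C_1 \rightleftharpoons C_p . $$

Each cluster is characterized quantum-chemically — adiabatic association
energy, harmonic wavenumbers, principal moments of inertia, volume — and
contributes independent electronic, translational, rotational and
vibrational partition functions to the canonical partition function

$$ Q = \prod_p \frac{1}{N_p!}\, q_p^{N_p}, \qquad
   q_p = q^{elec}_p\, q^{trans}_p\, q^{rot}_p\, q^{vib}_p . $$

Two empirical parameters connect the cluster gas to a condensed phase:

* **`amf`** (J m$^3$ mol$^{-2}$): an attractive mean-field energy
  $\epsilon^{mf}_p = -a_{mf}\, i_p\, \rho$ per mole of cluster, with $\rho$
  the total monomer density. It stabilizes dense configurations and is the
  main handle on the transition temperature.
* **`bxv`** (dimensionless): the translational partition function sees only
  the *accessible* volume $V - V_{excl}$ with
  $V_{excl} = b_{xv} \sum_p N_p v_p$. It controls the liquid density.

`amf = 0, bxv = 1` is the parameter-free cluster-gas model (QCE(0)).
Neither populations nor volume are inputs: the volume satisfies the
pressure constraint $P = k_B T\, \partial \ln Q / \partial V$ and the
populations the equal-chemical-potential condition
$\mu_1 / i_1 = \dots = \mu_N / i_N$.

## Partition functions

Translation, rotation and vibration use the standard particle-in-a-box,
rigid-rotor and harmonic-oscillator forms. Zero-point energy lives in the
vibrational partition function (factor $e^{-\theta/2T}$ per mode), never in
the electronic energy, so each term has one unambiguous home. Electronic
degeneracy is fixed at 1 (closed-shell clusters).

### The mRRHO vibrational treatment

Low-frequency modes of hydrogen-bonded clusters are internal rotations
rather than stiff oscillations; the harmonic form badly misestimates their
entropy. The modified rigid-rotor–harmonic-oscillator model interpolates
per mode between the harmonic oscillator and a one-dimensional free rotor
with an effective moment of inertia,

$$ \mu(\omega) = \frac{\hbar}{4\pi \nu}, \qquad
   \mu' = \frac{\mu \bar I}{\mu + \bar I}, \qquad
   q^{HR} = \sqrt{\frac{2 \mu' k_B T \pi}{\hbar^2}} , $$

where $\nu = c\tilde\omega$ is the mode frequency in s$^{-1}$ (this reading
of the frequency-to-moment conversion is the dimensionally consistent one)
and $\bar I$ is the cluster's average moment of inertia — by default the
arithmetic mean of the three principal moments. The reduction against
$\bar I$ caps the rotor at the cluster's overall rotation as
$\omega \to 0$. Mixing uses the switching function

$$ f(\omega) = \left(1 + (\omega_0/\omega)^4\right)^{-1}, $$

with a user-chosen rotor cutoff $\omega_0$ (cm$^{-1}$): `omega0 = 0`
disables the correction exactly; 50 cm$^{-1}$ is a sensitive choice in the
commonly recommended 20–100 cm$^{-1}$ range and 100 cm$^{-1}$ an upper
limit. Mixing is performed on logarithms (the interpolation is a product of
powers), and the zero-point factor is weighted with the harmonic branch
only, so the $\omega_0 \to \infty$ limit is the clean free-rotor product.
Whether ZPE should be damped together with the harmonic branch is a
genuinely open modelling question; weighting it by $f$ keeps both limits
exact, which is the property the engine's tests rely on.

## The coupled equilibrium

With Stirling's approximation ($\ln N! = N \ln N - N$; populations are of
Avogadro scale, so the approximation is exact for all practical purposes)
the equilibrium condition gives the mass-action law

$$ \ln N_p = \ln \tilde q_p + i_p\,(\ln N_1 - \ln \tilde q_1), $$

closed by the monomer balance $\sum_p i_p N_p = N_A\, n_{tot}$. The single
unknown $\ln N_1$ is found by Newton iteration on the log-sum-exp form of
the balance, which is convex and strictly increasing — convergence is
monotone and populations spanning hundreds of orders of magnitude are
handled exactly as well as order-one ones, because *all* population
arithmetic is done in log space.

One subtlety deserves emphasis. The chemical potential
$\mu_p = \partial A / \partial N_p$ of this model contains, besides the
familiar $-k_B T (\ln q_p - \ln N_p)$, a crowding term: adding a cluster
shrinks the accessible volume of *every* cluster by $b_{xv} v_p$, so

$$ \frac{\mu_p}{-k_B T} = \ln q_p - \ln N_p -
   \frac{N_c\, b_{xv}\, v_p}{V - V_{excl}} . $$

The engine includes this term in the effective $\ln \tilde q_p$ entering
the mass action. Without it the Gibbs energy is not stationary with
respect to the populations, and the Gibbs–Helmholtz identity
$d(G/T)/d(1/T) = H$ fails at the $10^{-3}$ level in the liquid branch; with
it the identity holds to $\sim 10^{-8}$ everywhere, which the test suite
checks. Because cluster volumes are nearly proportional to cluster size,
the term is almost completely absorbed by the monomer-balance multiplier
and moves the observables themselves only marginally (the transition
temperature of the built-in test fluid shifts by less than 0.01 K).

### Volume equation

At fixed populations the pressure constraint is the cubic

$$ P V^3 - (P V_{excl} + R T n_c)\, V^2 + a_{mf} n_{tot}^2\, V
   - a_{mf} n_{tot}^2 V_{excl} = 0 , $$

whose real roots above $V_{excl}$ (at most three: gas, liquid, and an
unstable middle root) are obtained with `polyroot()` and polished by Newton
steps. The test suite verifies every returned root against central finite
differences of the full $\ln Q$ — the analytic cubic is never trusted
blindly.

### Self-consistency, damping, and branch selection

`self_consistent_state()` alternates the population solve (at fixed
volume) with the volume solve (at fixed populations, choosing the root
nearest the current volume) until the relative change in the volume and in
every population falls below $10^{-9}$ (at most 500 iterations). Population
updates are damped by successive substitution — a convex combination with
factor 0.5, dropping to 0.25 after a divergent step — because undamped
substitution oscillates near the binodal. The convex combination is taken
in linear population space, where it preserves the monomer balance at
every iterate (a geometric/log-space mean does not: it leaks mass whenever
the old and proposed distributions disagree strongly, which is exactly the
situation early in a cold-start solve).

Two fixed seeds probe the two phases: the ideal-gas volume
($V = n_{tot} R T / P$, all-monomer start) and a packed-liquid volume
($1.1 \times b_{xv}$ times the summed monomer eigenvolume). The stable
state at a temperature is the converged state of minimal
$G = -k_B T \ln Q + P V$; ties within $10^{-9}$ relative are resolved
toward the larger volume (the entropically safer branch). Isobar scans
additionally warm-start each temperature from the previous stable state.

### Transition detection

Along an isobar the vapor–liquid transition appears as a discontinuous
volume jump. The scan locates the largest relative volume jump between
adjacent grid points; a jump above 0.5 (far above numerical noise — the
branches typically differ by two orders of magnitude) is refined by
bisection on the temperature of the Gibbs branch switch down to a bracket
of 0.01 K, and the midpoint is reported. No jump above the threshold means
"no transition", which is a regular outcome (e.g., for a pure monomer
gas), not an error.

## Observables

Internal energy uses the analytic $k_B T^2\, \partial \ln Q/\partial T$ at
fixed volume and populations: $\tfrac32 k_B T$ for translation and
nonlinear rotation, the harmonic-mode formula including ZPE weighted by
$f$, $\tfrac12 k_B T$ per hindered-rotor branch weighted by $1-f$, plus
electronic and mean-field energies. Then $S = U/T + k_B \ln Q$,
$H = U + PV$, $G = H - TS$; everything is reported per mole of monomer.
The heat capacity is a central finite difference of $H$ over re-solved
states at $T \pm 0.05$ K — at constant *pressure*, with the volume
re-equilibrated, because the isobar is a constant-pressure object.

**Ionic product.** Clusters flagged as containing separated ion pairs
contribute an ion concentration $c = \sum_p z_p N_p / V$; with exactly one
pair per flagged cluster the cation and anion concentrations are equal and
$K_w = c^2$. Concentrations are expressed in mol L$^{-1}$ against the
1 mol L$^{-1}$ standard state — the convention under which ambient water
has $pK_w \approx 14$. A set without populated ion-pair clusters yields
$K_w = 0$ and the sentinel $pK_w = +\infty$.

**Vaporization quantities.** The direct vaporization enthalpy is
$H_{gas} - H_{liq}$ with both branches re-solved exactly at the refined
transition temperature. Independently, `transition_curve()` collects
$(P, T_{trs})$ pairs over a pressure grid (default: geometric, 11 points
from 0.095898 to 4.7572 bar) and `fit_vaporization_enthalpy()` performs
ordinary least squares of $\ln(P/P^\circ)$ on $1/T$ ($P^\circ$ = 1 bar),
treating $\Delta H_{vap}$ as temperature-independent over the fitted range
(the integrated Clausius–Clapeyron relation); $\Delta H_{vap} = -R \times$
slope. The two routes agree within a few per mille on the built-in test
fluid because its vapor is essentially monomeric; for a strongly clustered
vapor the Clausius–Clapeyron estimate refers to moles of *gas particles*
rather than monomers and the two can legitimately differ.

**Vaporization entropy below the transition.** The liquid branch is
evaluated directly; the (hypothetical) vapor entropy below $T_{trs}$ comes
from an ordinary least-squares line fitted to the gas-branch $S(T)$ over
the first 30 K above the transition, where it is very nearly linear. The
window is configurable; widening it from 30 to 50 K moves the extrapolated
value by well under 2 J mol$^{-1}$ K$^{-1}$ on the test fluid. The
extrapolation is applied to $S$ itself rather than to $G$ — the entropy is
the closer-to-linear quantity over such windows.

## Parameter optimization

`optimize_parameters()` fits `(amf, bxv)` to a target density at a
reference temperature (default 298.15 K) and a target transition
temperature, minimizing the equally weighted sum of squared *relative*
deviations (the two observables have incommensurate units; relative
deviations make an unweighted sum meaningful — the weights are
configurable). The optimizer is a downhill simplex with the textbook
coefficients (reflection 1, expansion 2, contraction 1/2, shrink 1/2),
run in scaled coordinates $(a_{mf}/2,\ (b_{xv}-0.5)/1.5)$ so both
directions have comparable step sizes over the admissible box
$a_{mf} \in [0, 2]$ J m$^3$ mol$^{-2}$, $b_{xv} \in [0.5, 2]$.
Out-of-bounds vertices are evaluated at the clamped point plus a
squared-distance penalty, which repels the simplex from the boundary
without discontinuities. Convergence requires a simplex diameter below
$10^{-4}$ in scaled coordinates *and* an objective spread below
$10^{-10}$; an exhausted budget (default 200 evaluations) returns the best
vertex flagged as unconverged. A failed scan or missing transition at a
vertex contributes a $10^6$ penalty instead of an exception, so the
simplex can walk out of infeasible regions. The whole procedure is
deterministic: identical inputs give bit-identical traces.

## The synthetic cluster sets

Real QCE studies consume cluster sets from quantum-chemical calculations,
which are outside this package's scope (it reads them from a plain-text
descriptor format instead). For development and testing, three
deterministic generators are provided:

* `make_monomer_only()` — a water-like monomer (modes 1595/3657/3756
  cm$^{-1}$, experimental-style moments of inertia, $\sigma = 2$). With
  `amf = 0` and no excluded volume the engine must reproduce ideal-gas
  behavior and the closed-form RRHO entropy exactly.
* `make_monomer_dimer()` — the smallest nontrivial equilibrium, with a
  closed-form quadratic solution (`monomer_dimer_oracle()`) used as an
  independent oracle.
* `make_pseudo_water()` — a 15-cluster fluid (sizes 1–10 plus five
  ion-pair isomers of sizes 5–9) with strongly cooperative binding: the
  per-monomer association energy follows
  $e(i) = e_\infty (1 - 1/i)^3$ with $e_\infty = -75$ kJ mol$^{-1}$, so
  small clusters are shallow (the vapor stays essentially monomeric, as
  for water) while large clusters approach a liquid-like cohesive energy.
  Clusters of size $\ge 3$ carry six intermolecular modes drawn uniformly
  in 20–150 cm$^{-1}$, so both common rotor cutoffs (50 and 100 cm$^{-1}$)
  engage; the monomer and dimer have no mode below 100 cm$^{-1}$ and are
  therefore untouched by the mRRHO switch. Ion-pair isomers share their
  regular sibling's backbone energy plus a +60 kJ mol$^{-1}$
  charge-separation penalty, keeping their populations many orders of
  magnitude below the regular clusters, as appropriate for
  self-dissociation. All randomness comes from an explicitly seeded
  Lehmer (MINSTD) generator — a named, cross-language-reproducible
  algorithm, deliberately independent of R's global RNG — and the default
  set (seed 42) is additionally committed as a descriptor file under
  `inst/extdata/`, with a test asserting generator/file agreement so the
  two cannot drift apart silently.

At the reference parameters `(amf, bxv) = (0.20, 1.50)` and 1 atm the
default set exhibits a single vapor–liquid transition near 364 K, a liquid
density near 640 kg m$^{-3}$ at 298 K, and $pK_w \approx 19$; these
conditions were fixed once, when the generator was designed, and are the
study conditions for the whole test suite.

What the synthetic sets deliberately do **not** emulate: real water
frequencies beyond the monomer, anharmonicity, conformer multiplicity,
basis-set or dispersion effects, or any particular published cluster
ensemble. Passing tests demonstrate that the engine solves its model
correctly — not that the synthetic fluid is water.

## Numerical choices, in one place

* Constants: CODATA-2018, collected in `qce_constants`.
* Internal units: strictly SI; file formats use kJ/mol, cm$^{-1}$,
  amu Å$^2$, Å$^3$, amu, bar.
* Energies are stored as association energies (monomer $\equiv$ 0);
  absolute energies in input files are re-referenced on load, avoiding
  catastrophic cancellation downstream.
* Rotational symmetry numbers default to 1 when a descriptor omits them
  (σ only shifts $\ln q^{rot}$ by a constant per cluster; for fitted
  `amf`/`bxv` its main effect is absorbed into the fit).
* Population arithmetic in log space end to end; mass balance enforced to
  $10^{-10}$ relative; self-consistency to $10^{-9}$ relative.
* Gibbs ties ($< 10^{-9}$ relative) break toward the larger volume.
* Transition threshold 0.5 relative volume jump; bisection to 0.01 K.
* Heat capacity: central differences at $T \pm 0.05$ K; Gibbs–Helmholtz
  self-checks at $T \pm 0.1$ K.
* Test problem sizes: 301-point ideal-gas isobars, 73-point fixture
  isobars at 5 K steps, 11-pressure Clausius–Clapeyron grids, 50-state
  consistency sweeps, and a single 200-evaluation optimizer recovery —
  sizes chosen to exercise every code path at desk scale.

## Known limitations

* Single-component fluids only; the descriptor format has no mixture
  support.
* Two seeded branches (gas/liquid); exotic multi-minimum scenarios with
  more than two coexisting branches would need additional seeds.
* No spinodal or critical-point analysis; very close to a critical point
  the volume-jump detector will simply report no transition.
* The hindered-rotor form carries no zero-point term and no torsional
  eigenvalue treatment; frequencies are taken as supplied (pre-scaled if
  desired).
* Low temperatures are bounded by the validity of Boltzmann statistics,
  as for any QCE treatment.
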