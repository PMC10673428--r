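---
title: "Models and methods in unfoldkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in unfoldkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unfoldkit)
```

unfoldkit characterizes the conformational stability of a small protein
domain from two complementary directions: equilibrium thermodynamic models
fitted to denaturation data (pH titrations, chemical and thermal
denaturation curves, thermal-shift fluorescence traces and DSC thermograms),
and a purely mechanical, graph-rigidity simulation of thermal unfolding run
on a structure. This vignette explains the models, the parameters that
matter, the synthetic data used to exercise everything, and the numerical
and design choices behind the implementation.

## Equilibrium models

### pH titrations

A spectroscopic signal that mixes the contributions of a protonated and a
deprotonated species follows the Hill model

$$X(\mathrm{pH}) = \frac{X_a + X_b\,10^{\,n(\mathrm{pH} - pK_a)}}
                        {1 + 10^{\,n(\mathrm{pH} - pK_a)}},$$

where $X_a$ and $X_b$ are the intrinsic acidic and basic signals, $pK_a$
the apparent midpoint and $n$ the Hill coefficient. At
$\mathrm{pH} = pK_a$ the signal is $(X_a + X_b)/2$ for every $n$; as
$n \to \infty$ the model approaches a two-level step. `fitTitration()`
estimates all four parameters; a Hill coefficient near 1 is the expected
outcome for a single titrating group.

### Chemical and thermal denaturation

Two-state transitions are modeled through the equilibrium constant
$K = e^{-\Delta G / RT}$ with $R = 1.9872\times10^{-3}$ kcal mol$^{-1}$
K$^{-1}$ and the observed signal

$$X = \frac{X_N + X_D\,e^{-\Delta G/RT}}{1 + e^{-\Delta G/RT}},$$

with both intrinsic signals linear in the abscissa (denaturant
concentration or temperature). For chemical denaturation the linear
extrapolation model supplies
$\Delta G = m([D]_{1/2} - [D])$; for thermal denaturation the
Gibbs–Helmholtz expression

$$\Delta G(T) = \Delta H_m\left(1 - \frac{T}{T_m}\right)
  - \Delta C_p\left(T_m - T + T\ln\frac{T}{T_m}\right)$$

is evaluated in kelvin. Because denaturations of marginally stable domains
are typically irreversible, every fit result carries an explicit caveat:
the estimates are *apparent* parameters and no Gibbs energy of folding is
derived from them. $\Delta C_p$ is a free parameter by default in
`fitThermal()` but can be fixed (`fix_dCp = 0` gives the plain van't Hoff
form), because a van't Hoff $\Delta C_p$ from one irreversible curve is
weakly identified.

### Thermal-shift traces and DSC thermograms

A thermal-shift (differential scanning fluorimetry) trace is the
population-weighted sum of two temperature-linear baselines,
$F(T) = P_N F_N(T) + P_U F_U(T)$, fitted by `fitThermofluor()` for
$(T_m, \Delta H(T_m), \Delta C_p)$ plus four baseline parameters. The
fitted $T_m$ is invariant under overall signal scaling, so traces recorded
at different protein concentrations yield the same midpoint.

DSC thermograms of a protein with two energetic domains are described by
the two-transition partition function

$$Q(T) = 1 + K_1 + K_2 + K_1 K_2 = (1 + K_1)(1 + K_2),$$

four states: native (reference), two intermediates (one domain unfolded)
and unfolded (both domains unfolded). The mean excess enthalpy is
$\langle\Delta H\rangle = RT^2\,\partial \ln Q/\partial T
= P_1 \Delta H_1 + P_2 \Delta H_2 + P_{12}(\Delta H_1 + \Delta H_2)$, and
the excess molar heat capacity is its temperature derivative, implemented
in closed form as the Boltzmann variance of the state enthalpies,

$$\langle\Delta C_p\rangle(T) =
  \frac{\langle H^2\rangle - \langle H\rangle^2}{R T^2}
  + \sum_s P_s\,\Delta C_{p,s}.$$

The closed form is validated in the test suite against centered finite
differences of $\langle\Delta H\rangle$ rather than trusting either
derivation alone; with $\Delta C_p = 0$ the thermogram integrates exactly
to $\Delta H_1 + \Delta H_2$. The sequential three-state alternative
($Q = 1 + K_1 + K_1 K_2$) is available through
`fitDsc(model = "three_state")`; the two models coincide whenever the
second equilibrium constant is negligible at the temperatures where the
first is active, i.e. for well-separated transitions.

Population analyses use $\Delta C_p = 0$ per transition. This matches the
pre-processing convention for thermograms whose heat-capacity step has been
removed with a progress baseline: the step then no longer appears as a
geometric feature, and the transition enthalpies absorb the remaining
temperature dependence. $\Delta C_p$ per transition remains available as a
fit parameter (`free_dCp = TRUE`).

`specificUnfoldingEnthalpy()` reports $1000(\Delta H_1 + \Delta H_2)/MW$
in cal g$^{-1}$, a packing-density style comparator between proteins. The
molecular weight is always an explicit argument — the function never
guesses a construct mass.

### Fitting strategy

All fits use Levenberg–Marquardt least squares (minpack.lm). Midpoint
seeds come from the abscissa of the largest smoothed numerical derivative
(raw point-to-point derivatives are noise-dominated on dense grids);
baseline seeds from the terminal 20% of points at each end. Thermal-type
fits retry from a small set of alternative midpoint starts (window
quantiles) and keep the converged candidate with the smallest residual
standard deviation. DSC fits seed the two melting temperatures at the two
largest local maxima of the lightly smoothed thermogram and the enthalpies
from the peak heights via the two-state relation
$\Delta H^2 \approx 4 R T_m^2\,C_{p,\max}$; transitions are relabeled
after fitting so that $T_{m,1} \le T_{m,2}$.

Degenerate inputs are handled explicitly rather than returned as
pseudo-fits: constant titration signals are an error (unidentifiable);
flat or linear chemical and thermal curves come back as flagged
non-converged results. A chemical fit is additionally rejected when the
fitted midpoint lies outside the measured window, when the implied 10–90%
transition width $2RT\ln 81/m$ exceeds it, or when the transition
amplitude is under 10% of the signal range — all three are signatures of a
trend masquerading as a sigmoid.

## Synthetic data

The generator module produces every input the pipeline consumes:
Hill titrations, two-state chemical and thermal curves, thermal-shift
traces, one- or two-transition DSC thermograms, and poly-alanine helix
structures. Noise is additive, homoscedastic and Gaussian, seeded, with
defaults of 1% of the noiseless signal range for curves and
0.2 kcal mol$^{-1}$ K$^{-1}$ for thermograms; real measurement error is
neither reported for this kind of experiment nor exactly Gaussian, so
these defaults are stand-ins chosen at the scale of routine
spectrofluorimeter and capillary-DSC noise. Every synthetic object stores
its generating ("truth") parameters in its metadata, which is what the
recovery tests assert against. With `sd = 0` the generated curve equals
the model evaluation bit for bit.

What the generator does *not* emulate: instrument drift, scan-rate
effects, aggregation at high temperature, raw per-pH emission spectra, or
SEC chromatograms. Passing recovery tests therefore demonstrates that the
fitters are consistent and precise under the stated statistical model, not
that they are robust to every pathology of real traces.

The helix fixture builds an ideal poly-alanine backbone
(N, H, C$\alpha$, C$\beta$, C, O) by internal-coordinate chain extension
with standard literature geometry (bond lengths N–C$\alpha$ 1.458 Å,
C$\alpha$–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å, C$\alpha$–C$\beta$
1.521 Å, N–H 1.01 Å; angles C–N–C$\alpha$ 121.7°, N–C$\alpha$–C 111.2°,
C$\alpha$–C–N 116.2°; $\omega$ = 180°), default dihedrals
$(\phi, \psi) = (-57°, -47°)$. The amide hydrogen lies in the peptide
plane along the outward bisector of the N–C(i−1) and N–C$\alpha$ bonds;
the first residue has a free N terminus and carries none. The
construction is fully deterministic. An optional seeded coordinate jitter
(`jitter_sd`, Å) exists because the perfectly symmetric helix is
degenerate: all its i→i+4 hydrogen bonds have *identical* energy, so the
entire network would dissolve in a single energy step. A small jitter
(0.08 Å in the examples) spreads the bond energies and restores the
gradual, hierarchical breakup that real, irregular structures show.

## Constraint-network rigidity analysis

### Network construction

Atoms are rigid bodies with six degrees of freedom. Covalent bonds and
hydrogen bonds each place five bars between their two bodies (removing
five of the six relative degrees of freedom and leaving the dihedral
rotation); hydrophobic tethers place two bars. Hydrogen bonds connect the
donor and acceptor heavy atoms and carry a Mayo-style distance-and-angle
energy

$$E_{HB} = V_0\left[5\left(\frac{d_0}{d}\right)^{12}
  - 6\left(\frac{d_0}{d}\right)^{10}\right]
  \cos^2\theta\; e^{-(\pi-\theta)^6},$$

with $d$ the donor–acceptor distance, $\theta$ the donor–H–acceptor
angle, $V_0 = 8$ kcal mol$^{-1}$, $d_0 = 2.8$ Å, a 3.6 Å distance gate
and a 90° angular gate; only favorable candidates ($E_{HB} < 0$) are
kept. For structures without hydrogens a distance-only variant of the
score is available. Hydrophobic tethers join carbon/sulfur pairs from
residues at least two apart within the sum of united-atom van der Waals
radii (C 1.85 Å, S 1.95 Å) plus 0.25 Å. During the simulated unfolding
only hydrogen bonds are diluted — at energy $E$ the network keeps exactly
the bonds with $|E_{HB}| \ge E$ — while covalent bonds and tethers
persist.

### Pebble game and indexes

Rigidity is decomposed with the (6,6) pebble game for body-and-bar
multigraphs: every body holds six pebbles, a bar is independent when a
seventh pebble can be gathered on its endpoints, and an accepted bar
consumes one. Free pebbles equal $6n$ minus the rank of the generic
body-bar rigidity matroid; internal floppy modes are the free pebbles
minus the six trivial rigid-body motions. Two bodies share a rigid
cluster exactly when no seventh pebble can be freed on the pair; for
body-bar frameworks this mutual-rigidity relation is an equivalence, so
the clusters are a genuine partition, recovered by pair tests on the
network edges plus a union–find. The test suite checks the game against
an independent oracle — the rank of a randomly embedded rigidity matrix —
on over a hundred random small networks, and checks that the
decomposition is invariant under body permutation.

The unfolding sweep (`simulateUnfolding()`) walks $E$ from 0 upward in
0.1 kcal mol$^{-1}$ steps and reports three global indexes:

* $\Phi$, floppy mode density: internal floppy modes over $6n - 6$;
  non-decreasing, since constraints are only removed.
* $\Sigma$, cluster configuration entropy:
  $-\sum_s w_s \ln w_s$ with $w_s = s\,n_s/N$ over the distinct rigid
  cluster sizes. It is zero for one all-encompassing cluster, zero again
  when every body is a singleton, and — because it measures the disorder
  of the *size distribution* — zero for any monodisperse decomposition.
  It peaks while clusters of many different sizes coexist, which is the
  signature of the rigidity transition. On the minimal helix fixture a
  constant background contributes to $\Sigma$ at low $E$: the carbonyl O,
  amide H and C$\beta$ bodies hang on single rotatable bonds and are
  permanent singletons, something a densely packed protein core largely
  avoids.
* $\Pi$, rigidity order parameter: the fraction of the bodies of the
  giant rigid cluster at $E = 0$ that still share one rigid cluster.
  Defined this way it is provably non-increasing (cluster partitions only
  refine as constraints disappear).

Because the network only changes at the discrete bond strengths, the
sweep computes one decomposition per distinct bond set and maps it back
onto the energy grid; the pebble game runs incrementally from the
sparsest network down, inserting bonds strongest-first.

Transition detection uses the largest single-step change — drop for
$\Pi$, rise for $\Sigma$ — with ties resolved to the lowest energy; flat
or perfectly linear traces return a no-transition flag. The energy
coordinate maps to temperature through the affine relation
$T(\mathrm{K}) = 300 + 20E$ (returned in °C, exactly invertible), so
$E = 0$ corresponds to 26.85 °C and each 0.1 kcal mol$^{-1}$ step to
2 °C.

### Fuzzy ensembles and local indexes

A single network topology is brittle: its transition energies are
hypersensitive to the input structure. `fuzzyEnsemble()` therefore
perturbs each hydrogen-bond energy with seeded Gaussian noise of standard
deviation `sigma_E` (default 0.2 kcal mol$^{-1}$; bonds driven
unfavorable are dropped for that topology, mimicking constraints
randomly broken in the native state), repeats the sweep over
`n_topologies` networks (default 500) and reports each index's
transition energy as mean ± SD. The exact perturbation scheme used by
rigidity web servers is unpublished, so this Gaussian scheme is this
package's explicit stand-in.

Per residue, `localIndexes()` reports: $P$ (percolation index), the
lowest $E$ at which the residue's C$\alpha$ leaves the giant cluster;
$R$ (rigidity index), the mean $E$ at which the residue's backbone
covalent constraints stop sharing a rigid cluster; and $F$ (weak-spot
frequency), the fraction of topologies in which the residue hosts — as
donor or acceptor — the weakest hydrogen bond removed at that topology's
$\Pi$ transition step. Termini, which hold little structure, show low
$P$ and $R$; a chain with no hydrogen bonds has $P = R = 0$ everywhere.
Whether $P \le R$ holds universally is not asserted as an invariant; it
is simply observed on the fixtures. `annotateStructure()` maps $P$ or
$R$ onto the structure as PDB B-factors for visualization; the values do
not depend on the snapshot energy, which only labels the file.

## Problem sizes and reproducibility

The bundled tests and the acceptance script run, by choice, on compact
problems that exercise every code path at full fidelity: denaturation
grids of 21–326 points matching routine instrument resolution, helices of
8–12 residues (48–71 bodies), ensembles of 20–100 topologies, and
property suites of 100+ random networks of up to 12 bodies against the
rank oracle. All randomness flows from explicit seeds (one root seed with
deterministically derived per-stage sub-seeds in the pipeline), and the
pipeline manifest records md5 checksums of every output so that identical
configurations are verifiably identical.

## Known limitations

* Apparent parameters only: irreversible denaturations preclude true
  equilibrium thermodynamics, and the package deliberately reports no
  folding Gibbs energy from chemical fits.
* The rigidity module predicts propensities, not motions: it identifies
  where and in which order rigidity is lost, but not the amplitude of the
  resulting movements, nor whether detached substructures drift apart or
  stay collapsed.
* Salt bridges, aromatic stacking and side-chain hydrogen-bond donors
  beyond standard backbone atom names are not modeled; the bundled
  fixtures are poly-alanine backbones.
* Kinetic (scan-rate-dependent) irreversible DSC models and absolute
  heat-capacity baselines are out of scope; thermogram fitting assumes
  baseline-subtracted excess heat capacity.
* The cluster-entropy normalization, weak-spot definition and fuzzy
  perturbation scheme are this package's documented choices among several
  unpublished server-side conventions; transition energies of a specific
  protein structure should be compared across tools with that in mind.
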