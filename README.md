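# unfoldkit

Equilibrium unfolding thermodynamics and constraint-network rigidity
analysis of protein stability, in R.

Marginally stable protein domains — the N-terminal p53-binding domain of
MDM2 is the motivating case — unfold through intermediates, irreversibly,
and over a narrow pH window, which makes their stability hard to pin down
with any single technique. unfoldkit is for biophysicists who combine
spectroscopic denaturation experiments (intrinsic/ANS fluorescence, far-UV
CD), thermal-shift assays and differential scanning calorimetry with a
structure-based mechanical picture of the unfolding process, and who want
all of those analyses as tested, seeded, scriptable code.

The package has three layers:

* **Equilibrium models and fitters.** Hill pH titrations
  `X = (X_a + X_b 10^{n(pH−pKa)}) / (1 + 10^{n(pH−pKa)})`; two-state
  chemical denaturation under the linear extrapolation model
  `ΔG = m([D]_{1/2} − [D])`; Gibbs–Helmholtz thermal curves
  `ΔG(T) = ΔH_m(1 − T/T_m) − ΔC_p(T_m − T + T ln(T/T_m))`; two-state
  thermal-shift traces `F(T) = P_N F_N(T) + P_U F_U(T)`; and
  two-transition DSC deconvolution with partition function
  `Q = (1 + K_1)(1 + K_2)`, analytic excess heat capacity and
  four-state population analysis (a sequential three-state variant is
  included for comparison). All fits are Levenberg–Marquardt with
  heuristic initialization and explicit failure flags; all report
  *apparent* parameters with an irreversibility caveat.
* **Rigidity analysis.** A body-and-bar constraint network (covalent and
  hydrogen bonds five bars, hydrophobic tethers two), Mayo-style
  hydrogen-bond energies, and a (6,6) pebble game that dilutes hydrogen
  bonds from weakest to strongest in 0.1 kcal/mol steps, reporting the
  floppy mode density Φ, cluster configuration entropy Σ and rigidity
  order parameter Π, per-residue percolation/rigidity/weak-spot indexes
  (P, R, F), fuzzy network ensembles, and the affine map
  `T(K) = 300 + 20·E` between dilution energy and temperature.
* **Synthetic data and pipeline.** Seeded generators for every input —
  curves with stored truth parameters, ideal poly-alanine helix fixtures
  with detectable backbone hydrogen bonds — plus CSV/PDB I/O and a
  deterministic, manifest-writing pipeline (`runPipeline()`).

## Worked example

Deconvolute a (synthetic, seeded) DSC thermogram generated at the
reference experimental conditions for this domain — transitions at 52.3 and
69.8 °C with enthalpies 55 and 50 kcal/mol, 0.2 kcal/mol/K noise:

```r
library(unfoldkit)

tg <- makeThermogram(list(TransitionParams(52.3, 55),
                          TransitionParams(69.8, 50)),
                     seq(25, 90, 0.2), NoiseSpec(0.2, seed = 1))
fit <- fitDsc(tg)
fit
#> DscFit (converged)
#>   Tm1            52.278  (se 0.0721)
#>   dH1            54.523  (se 0.265)
#>   Tm2            69.734  (se 0.107)
#>   dH2             49.81  (se 0.29)

df <- as.data.frame(fit@populations)
max(df$intermediate1)          # 0.785 near 60.6 degC
max(df$intermediate2)          # < 0.02

specificUnfoldingEnthalpy(coef(fit)[["dH1"]], coef(fit)[["dH2"]],
                          MW = 11170)
#> 9.34  (cal/g)
```

Both melting temperatures come back within their standard errors of the
generating values, the first intermediate peaks just under 80% around
60 °C while the second stays below 2%, and the specific unfolding
enthalpy lands at ~9.3 cal/g for the given construct mass.

The rigidity side runs off a bundled helix fixture (or any single-model
PDB via `readStructure()`):

```r
hx <- makeHelixStructure(HelixFixtureSpec(12), jitter_sd = 0.08,
                         jitter_seed = 7)
tr <- simulateUnfolding(hx)          # E sweep, 0.1 kcal/mol steps
detectTransition(tr, "pi")           # collapse of the giant rigid cluster
energyToTemperature(0.45)            # 35.85 degC
ens <- fuzzyEnsemble(hx, n_topologies = 50, sigma_E = 0.2, seed = 5)
as.data.frame(ens@profile)           # per-residue P, R, F
```

A thin command-line front end over the same functions is installed at
`system.file("cli", "unfoldkit.R", package = "unfoldkit")` with
subcommands `simulate`, `fit-titration`, `fit-chemical`, `fit-thermal`,
`fit-thermofluor`, `fit-dsc`, `dsc-populations`, `rigidity-unfold`,
`rigidity-ensemble` and `run --config config.json`.

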