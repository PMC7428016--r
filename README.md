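# drfkit

Receptor-mediated toxicity of environmental pollutants begins with a
ligand–receptor encounter, and before any docking pose forms, long-range
electrostatics have already decided the ligand's approach: the charged
residues of the receptor (for the aryl hydrocarbon receptor, AhR, a net
charge of about +4 at pH 7.4) torque the ligand's dipole into alignment,
fixing which face of the molecule — and which of its reactive carbons —
arrives first. `drfkit` implements the **directional reactive (DR) model**,
which scores this pre-binding configuration and uses it as an in-silico
indicator of relative potency for planar aromatic ligands such as chrysene
and its benzo-, dibenzo-, methyl- and hydroxy-substituted homologues.

The core quantity is the **directional reactivity factor**

```
DRF = C_LR · Q_R,net · Σ_n  F_n± · |D| · cos φ_n
```

summed over the ligand's *terminal sites* (carbons bonded to H or a
functional group), where `F_n±` is the condensed Fukui weight of the site's
carbon (`f⁺ = q(N) − q(N+1)`, `f⁻ = q(N−1) − q(N)`, mode chosen by the
receptor's charge sign under cytosolic-ion screening), `|D|` the molecular
dipole magnitude (Debye), `φ_n` the angle between the dipole line of action
and the site's bond direction, and `Q_R,net` the receptor net charge from
Henderson–Hasselbalch fractions at the assay pH. `C_LR` is constant across
ligands for one receptor and defaults to 1, so scores are relative model
units: ranks and signs are the meaningful output. The most reactive
carbon's placement is classed forward / perpendicular / backward
(F/P/B) relative to the dipole.

The package is for computational toxicologists and cheminformaticians who
have per-atom charge populations for the neutral, anion and cation states
(from any electronic-structure code) and want reactivity-based potency
rankings, plus the bioassay side: four-parameter log-logistic EC50 fitting
under the equal-efficacy/parallelism assumption, %BaP_max normalization,
and rank/regression statistics against the packaged transcriptions of the
published reference tables for the twelve chrysene homologues.

## Worked example

```r
library(drfkit)

## receptor side: AhR ligand-binding-domain charged-residue composition
q <- net_charge(c(H = 5, R = 10, K = 5, D = 5, E = 6), ph = 7.4)
print(q)
#> <receptor_charge> Q_net = +4.193 e at pH 7.40 (pKa table: classic, termini excluded)
#>   D       -4.9991
#>   E       -5.9958
#>   H       +0.1914
#>   K       +4.9960
#>   R       +9.9999
```

+4.19 e at pH 7.4: histidines are mostly deprotonated (+0.19 of a possible
+5), arginines and lysines essentially fully charged, matching the
published +4.1 for this receptor.

```r
## ligand side: a seeded synthetic fixture standing in for DFT output
fx <- random_drf_fixture(7)
res <- drf(fx$mol, fx$charges$neutral, fx$charges$anion, fx$charges$cation,
           q_net = q$net_charge, dipole = fx$dipole)
print(res)
#> <drf> fixture-seed7: DRF = 0.8258 (f_plus, Q_net = +4.19 e, |D| = 3.685 D, orientation F)
```

The positive receptor selects `f_plus`; the positive score with class `F`
says this fixture's most reactive carbon points along the dipole line of
action — a favorable approach geometry. Real inputs come from
`read_xyz()` + `read_charge_csv()` instead of the fixture generator.

```r
## model vs experiment across the twelve chrysene homologues
ref <- load_reference_tables()
association(ref$drf, ec50_printed_to_um(ref$ec50_h4iie),
            method = "spearman", transform = "reciprocal")
#> <association> spearman (reciprocal transform): rho = 0.9772, p = 4.64e-08, n = 12
head(rank_by_drf(ref[, c("compound", "drf")]), 3)
#>           compound   drf rank
#> 1 2-methylchrysene 27.97    1
#> 2 3-methylchrysene 13.66    2
#> 3 benzo[c]chrysene  9.75    3
```

DRF rank order agrees with the H4IIE-luc bioassay potency (1/EC50) at
ρ = 0.977; the top-ranked compound, 2-methylchrysene, is also the assay's
most potent (EC50 = 0.66 µM).

```r
## bioassay side: EC50 from a noisy simulated dose-response curve
cv <- simulate_dose_response(fixture_spec(seed = 1, planted_ec50 = 5, noise_sd = 5))
fit_ec50(cv)
#> <ec50_fit> fixture-seed1: EC50 = 4.551 uM (hill 1.311, bottom 0.3, top 94.6; 4PL)
```

A command-line surface (`netcharge`, `fukui`, `dipole`, `drf`, `rank`,
`compare`, `simulate`) is available via `drf_cli()` or the wrapper script
`inst/cli/drfkit.R`.

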