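---
title: "The directional reactive model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The directional reactive model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drfkit)
```

## The model

Before a small aromatic ligand docks into a cytosolic receptor such as the
aryl hydrocarbon receptor (AhR), long-range electrostatics dominate: the
receptor's ionized residues (screened by trapped cytosolic ions) exert a
torque on the ligand's dipole, aligning it along the line of force and
thereby fixing which face of the molecule arrives first. Whether that face
carries the molecule's reactive carbons then decides how favorable the
encounter is. The directional reactivity factor condenses this into

$$\mathrm{DRF} \;=\; C_{LR}\, Q_{R,\mathrm{net}}
  \sum_{n=1}^{\#A:X} F_n^{\pm}\, |\vec D| \cos\phi_n ,$$

where the sum runs over the ligand's *terminal sites* — heavy atoms bonded
to a hydrogen or a functional group — $F_n^{\pm}$ is the condensed Fukui
weight of the site's heavy atom, $\vec D$ the molecular dipole (Debye),
$\phi_n$ the angle between the dipole direction and the site's bond vector
$\hat n$, $Q_{R,\mathrm{net}}$ the receptor's net charge at the assay pH,
and $C_{LR} = 1/(4\pi\varepsilon_0\varepsilon_R r)$ a coupling that is
constant across ligands at equal ligand–receptor distance for one receptor.
Sites pointing away from the line of action ($\cos\phi_n < 0$) *reduce* the
score. Because $C_{LR}$ is an overall constant we default it to 1 and report
DRF in model units (Fukui × Debye × e); only relative scores and ranks are
meaningful, and the package deliberately does not try to reproduce absolute
published magnitudes, whose unit conventions (e.g. a dipole column printed
as "10² Debye") cannot be reconstructed.

### Fukui mode selection

The sign of the receptor charge picks the Fukui function. Cytosolic ions
accumulate around charged residues, so the approaching ligand effectively
sees the *opposite* of the receptor's net charge; for a net-positive
receptor ($Q_{\mathrm{AhR}} \approx +4$) the ligand's
nucleophilic-attack sites are engaged and $F^{+}$ is used, for a
net-negative receptor $F^{-}$. `select_fukui_mode()` implements exactly
this rule and errors on a zero charge unless an override is given — a
neutral receptor gives the model no directional information, and silently
picking a mode would hide that.

### Condensed Fukui functions

With partial charges $q_k$ for the $N$, $N{+}1$ and $N{-}1$ electron states
(any population analysis; the reference data used Hirshfeld populations),

$$f^+_k = q_k(N) - q_k(N{+}1), \qquad
  f^-_k = q_k(N{-}1) - q_k(N), \qquad
  f^0_k = \tfrac12 (f^+_k + f^-_k).$$

Each vector sums to one by charge conservation — a cheap, strong invariant
the test suite exploits. Negative entries can occur through orbital
relaxation; they are propagated as-is with a warning rather than clamped,
since clamping would silently break the sum rule. Whether hydrogen weight
should be folded into the bonded carbon is not decidable from per-carbon
tabulations alone; both modes are exposed and condensation is the default,
matching how per-carbon maxima are usually reported.

### Terminal sites and geometry

"Terminal atom" is interpreted as a carbon bearing an exocyclic substituent,
with $\hat n$ along the carbon→substituent bond; for multi-atom groups the
first atom defines the direction (C→C for methyl, C→O for hydroxyl). Ring
membership comes from cycle detection on the bond graph; bonds are perceived
by the standard covalent-radius heuristic $d_{ij} \le 1.2\,(r_i + r_j)$,
adequate for idealized or DFT-optimized geometries (the scale factor is
exposed; 1.2 is the common default). All terminal sites enter the sum with
equal weight — nothing in the model distinguishes base-ring from added-ring
C–H sites.

### Orientation classes

The most reactive carbon's placement is summarized as forward (F),
perpendicular (P) or backward (B) using the mean $\cos\phi$ over the
maximum-Fukui site(s): F above $\tau$, B below $-\tau$, else P. The
threshold defaults to $\tau = \cos 75^\circ \approx 0.259$: the published
classification is qualitative, and a narrow perpendicular band is what
reproduces a "P" call for a base scaffold whose weak dipole is nearly
normal to the molecular plane while leaving clearly tilted cases F or B.
Ties among maximum-Fukui carbons are averaged, not broken. A zero dipole
gives no line of action; the score is 0 and the class defaults to P. The
argmax is taken over site-bearing carbons only, since per-carbon Fukui
maxima are defined for carbons bonded to H or functional groups.

### Receptor net charge

$Q_{R,\mathrm{net}}$ comes from Henderson–Hasselbalch fractions: at pH
$p$, a basic site of constant $K$ contributes $+1/(1+10^{\,p-pK})$, an
acidic site $-1/(1+10^{\,pK-p})$. For the AhR ligand-binding-domain
composition (5 His, 10 Arg, 5 Lys, 5 Asp, 6 Glu in 107 residues) the
classic biochemistry pKa set (D 3.65, E 4.25, C 8.3, Y 10.1, H 6.0,
K 10.5, R 12.5) gives +4.19 at pH 7.4, consistent with the published +4.1;
the exact published pKa set is not recoverable, so EMBOSS, Sillero and
Lehninger presets ship alongside and the package treats agreement within
±0.15 as the meaningful statement. Termini are included by default only
when the input is a single-chain sequence — a bare residue composition
does not imply one chain. Cys/Tyr contribute when present; they are
near-neutral at pH 7.4 but not exactly zero.

## Dose–response and association

EC50s are estimated with a four-parameter log-logistic curve

$$y = \mathrm{bottom} + \frac{\mathrm{top}-\mathrm{bottom}}
  {1 + 10^{\,h\,(\log_{10}\mathrm{EC}_{50} - \log_{10} d)}}$$

fit by Levenberg–Marquardt least squares. When a reference compound is
supplied the equal-efficacy/parallelism assumption is imposed: slope and
asymptotes are shared and only the midpoints differ. A negative-slope
optimum is mapped back to the equivalent positive-slope parameterization
(swap asymptotes), so the reported Hill coefficient is always positive.

`association()` offers squared Pearson correlation and Spearman's rank
correlation (mid-ranks for ties, two-sided p-values). The transform
(`identity`, `reciprocal`, `log10`) applies to the observed variable only —
model scores span negative values, where a reciprocal or log would be
meaningless; Pearson is in any case invariant to positive rescaling of
either variable after a log transform. The default comparison of packaged
scores against potency is Spearman on 1/EC50: the published regression's
exact transform and axis choices cannot be pinned down, so rank concordance
is the robust statement (ρ ≈ 0.977 over the twelve homologues, top
compound 2-methylchrysene).

## Synthetic fixtures

No deposited geometries, charge populations or raw assay data exist, so the
package generates its own study material deterministically from seeds:

* **Geometries** — cata-condensed fused hexagons (zigzag fusion by default,
  matching the angular scaffold of the chrysene family; linear acene
  fusion available), ideal bond lengths (C–C 1.40 Å, C–H 1.09 Å,
  C–O 1.36 Å, O–H 0.96 Å, C–CH₃ 1.50 Å), planar in *z* = 0. Peripheral
  positions can carry methyl or hydroxyl groups. The random fixture
  generator rejects substituent draws whose idealized groups would clash
  sterically (bay/ortho positions) using bond-degree sanity checks, and
  retries deterministically under the seed.
* **Charge states** — the neutral set is the minimum-norm solution (SVD
  pseudo-inverse) reproducing a planted in-plane dipole under the
  point-charge formula with zero total charge; anion and cation are the
  neutral set minus/plus planted Fukui distributions placed on heavy
  atoms. This guarantees exact round-trips (recovered Fukui within 1e−9,
  dipole within 1e−6) while staying independent of the engine under test.
  A dipole with an out-of-plane component is infeasible for in-plane point
  charges and raises an error rather than being silently projected.
* **Dose–response** — 10 fivefold serial dilutions from a 100 µM top dose
  (the published assay design), logistic mean with Hill slope 1.2, bottom
  0 and top 100 %BaP\_max, Gaussian noise of σ = 5 %BaP\_max, 3 replicates
  per dose. At these conditions the noise-free fit recovers the planted
  EC50 to machine precision and the median relative error over 200
  simulations is ≈ 8%.

What the fixtures do **not** emulate: real DFT charge distributions (planted
Fukui vectors are uniform-random, not physical), conformational flexibility,
out-of-plane dipole components of substituted scaffolds, assay-plate
artifacts, or inter-experiment variability. Passing tests therefore
demonstrate that the implementation computes the model correctly and
robustly — not that the model's chemistry is right for any particular
compound.

## Validation strategy and problem sizes

A deliberately naive brute-force oracle (`drf_bruteforce_oracle()`;
explicit loops, own bond perception, own cycle detection by edge-removal
reachability, no shared helpers) recomputes the score independently; the
engine agrees with it to < 1e−10 on 100 seeded random fixtures of 1–6
rings. Symmetry tests check exact antisymmetry under dipole negation and
under receptor-charge negation at fixed Fukui mode (negating the charge
also flips the mode selection, which is a model input change, not a
symmetry), invariance under joint rigid rotation of geometry and dipole,
and the zero-dipole degenerate case. Fukui conservation is asserted on the
same battery. These sizes (100 fixtures, 200 dose–response simulations)
were chosen as the smallest batteries that exercise every fixture regime
(ring counts, substituent types, both Fukui modes, both receptor signs)
while keeping Monte-Carlo noise on the summary statistics small.

## Known limitations

* Absolute DRF values are not comparable to published tables; only ranks
  and signs are.
* Bond perception is distance-based; it will mis-handle exotic geometries
  (organometallics, transition states) outside its intended domain.
* pKa values are sequence-context-free; structural pKa shifts are out of
  scope, which is why the receptor charge is reported with its pKa-table
  provenance.
* The EC50 fitter assumes a monotone sigmoid; biphasic or cytotoxic
  responses need pre-treatment.
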