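---
title: "Ranking stabilizing mutations from structure ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking stabilizing mutations from structure ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdstab)
```

## The problem

Primary thermostability predictors (empirical force fields such as FoldX,
or learned models) are good at discarding destabilizing point mutations but
rank the remaining, supposedly stabilizing candidates poorly.  In classical
engineering workflows a human expert therefore inspects short molecular
dynamics (MD) simulations of each candidate before committing to wet-lab
testing — slow, subjective, and irreproducible.  `mdstab` formalizes that
inspection: given a structure ensemble (MD snapshots, or any set of
conformers) of each mutant and of the wild type, it computes a set of
interpretable biophysical metrics, reports each as the mutant-minus-wild-type
difference, and aggregates them into a single composite score used to
re-rank the candidates.

The package deliberately stops at the ensemble boundary: it does not run or
convert MD simulations, and it does not build mutant structures.  Ensembles
come in as multi-model PDB files carrying CONECT bond records (or DCD
trajectories next to such a topology).  Two loud caveats follow from that
contract: inputs must already be protonated (there is no protonation
engine), and they must be whole-molecule — **no periodic-boundary imaging is
performed**, so a molecule split across a box boundary will produce garbage
distances.

## Selections

Every fluctuating metric is evaluated at up to three granularities: the
mutated residue itself, its *surrounding* (every protein residue with an
atom within 8 Å of the mutated residue — the radius commonly cited as the
optimal context for stability effects), and the whole protein.  The
whole-protein level is opt-in: on short trajectories it converges much more
slowly than the local selections and mostly adds noise.  Salt bridges are
the exception and are always counted on the whole protein, because they are
rare enough to be absent from most local selections.  Surrounding
membership is recomputed per frame for per-frame metrics (hydrogen
bonding); for trajectory-level quantities (RMSF, benchmark scores) the
frame-1 membership is used.  The choice of a *dynamic* surrounding matches
the per-frame averaging of the metrics themselves.

## Hydrogen-bond model

Detection is deliberately lenient — donor–acceptor distance ≤ 3.5 Å and
donor–hydrogen–acceptor angle ≥ 100° over all N/O/S donors (with a
covalent H) and N/O/S acceptors — because the subsequent energy filter is
what removes unrealistic geometries.  The energy of a detected bond is a
product of saturated ramps,

$$E = 25 \cdot S_{HA} \cdot S_{DHA} \cdot S_{HAX} \ \mathrm{kJ/mol},$$

with
$S_{HA} = \mathrm{clamp}\!\left(\frac{2.6 - \max(d_{HA},\,2.1)}{2.6-2.1}\right)$,
$S_{DHA} = \mathrm{clamp}\!\left(\frac{\min(\theta_{DHA},165)-100}{165-100}\right)$,
and $S_{HAX}$ the minimum over the acceptor's covalent neighbors of a 10°
ramp that opens at 85–95° for heavy neighbors and 75–85° for hydrogen
neighbors (heavy atoms hinder more, so the stricter window applies).  An
acceptor with no covalent neighbors is unhindered ($S_{HAX}=1$).  An ideal
bond is worth 25 kJ/mol; bonds at or below 6.25 kJ/mol are discarded.

Two refinements:

* **Bifurcation.**  When one hydrogen (or one acceptor) participates in two
  or more retained bonds, the strongest keeps its energy and every further
  bond is capped at 15 kJ/mol.  The cap centers on the shared hydrogen or
  acceptor — a donor heavy atom engaging through two *different* hydrogens
  (a water, a lysine amine) is not bifurcated.  This is what makes a water
  donating two ideal bonds worth 2 × 25 before the desolvation penalty.
  Ties between equal energies are broken by atom-index order, so capping is
  deterministic.
* **Water bridges.**  A water with ≥ 2 retained protein bonds forms a
  bridge with energy (sum of member energies) − 32.2 kJ/mol, the entropic
  cost of taking one water out of solution.  Arithmetically negative
  bridges are floored at 0; the model treats a marginal bridge as worthless
  rather than harmful.

The **unsatisfied count** compares the potential-partner set against the
atoms engaged in any retained bond.  The default partner set is all protein
N/O/S atoms plus their bound hydrogens; an alternative, narrower definition
(all oxygens plus hydrogen-free nitrogens) ships behind
`definition = "strict"` because both conventions are defensible and users
may want either.  Membership in a water-mediated bond satisfies an atom.
The per-mutation H-bond metrics are the frame-averaged totals (retained
protein–protein energies touching the selection, plus bridge energies
anchored in it; unsatisfied partners inside the selection), differenced
against the wild type.

## Flexibility

Backbone flexibility is the per-residue RMSF of Cα atoms after a global
least-squares superposition of all frames (reference: frame 1).  Sidechain
flexibility uses a *local* superposition on the backbone (N, CA, C, O) of
the residue and its two sequence neighbors, so backbone drift does not
contaminate the sidechain signal, and averages the RMSF of the residue's
non-backbone atoms.  Glycine returns 0 with a `no_sidechain` flag.

Raw sidechain RMSF is not comparable between amino acids or between a
buried tryptophan and an exposed serine, so it is normalized through
*benchmark curves* (below), keyed by amino acid × exposure class.  Exposure
classes derive from the trajectory-mean relative SASA of the residue
(observed SASA / reference SASA of the free amino acid): **buried** at
exactly 0 %, **partial** in (0, 20] %, **exposed** above 20 %.  The mean
(not per-frame) SASA is used so a residue's category is stable along the
trajectory.  The shipped reference table is the Tien et al. (2013)
theoretical maximum-ASA set — a documented stand-in, swappable through the
`ref_sasa` argument, and the classification is insensitive to the exact
table because only the 0 %/20 % boundaries matter.

## Hydrophobic exposure

Hydrophobic moieties are approximated as every atom in a C–C or C–H bond:
all carbons plus hydrogens bound to carbon.  Their summed, trajectory-mean
SASA per residue is scored against per-amino-acid benchmark curves (20
categories).  SASA is computed by Shrake–Rupley sphere sampling: probe
1.4 Å, Bondi van der Waals radii, 100 deterministic golden-spiral points
per atom (configurable).  One numerical subtlety: sphere sampling is not
natively invariant under rotation of the input.  Coordinates are therefore
first mapped to a canonical frame — centered, aligned to the principal
axes, with axis signs fixed by the coordinate skewness and the third axis
taken as the cross product of the first two — which makes the computed
areas exactly invariant under rigid-body motion instead of merely
invariant up to sampling noise.  Degenerate inputs (perfectly symmetric
point sets) could in principle flip an axis; protein coordinates are never
that symmetric.

## Benchmark curves

Expected distributions of sidechain RMSF (20 amino acids × 3 exposure
classes = 60 categories) and hydrophobic SASA (20 categories) are estimated
from any reference collection of ensembles — typically MD runs of a curated
protein set under the force field of interest, or, in tests, synthetic
samples.  Per category a Gaussian KDE with Silverman's rule-of-thumb
bandwidth ($h = 0.9\,\min(\hat\sigma, \mathrm{IQR}/1.34)\,n^{-1/5}$ — this
is exactly `stats::bw.nrd0`) is evaluated on a uniform 512-point grid over
$[0, \max x + 3h]$, scaled to a maximum of 1, and then made monotone
non-increasing by the suffix-maximum envelope $y_i' = \max_{j \ge i} y_j$.
The envelope "fills in" the left flank and any dip between modes, so only
*unusually high* flexibility or exposure is penalized — unusual rigidity or
burial is never rewarded beyond 1.  The grid resolution and range are the
package's own choice (the curves ship with their grids, so scoring is
self-consistent); 512 points make the interpolation error negligible
against the score noise.  Scoring interpolates linearly and clamps to the
endpoint values outside the stored range.  Curves serialize to plain CSV
(`category,x,y`), which is also the compatibility surface for externally
generated benchmark files; loading re-validates the invariants.

Categories with fewer than two distinct samples are skipped and recorded in
a manifest; they fail loudly at score time rather than silently at build
time, since a missing category only matters if a residue of that category
is actually scored.

## Composite score

Raw metric deltas are assembled into a table (rows = mutations), each
column divided by its *population* standard deviation over the mutation set
— without centering, so 0 remains the wild-type reference — and multiplied
by a fixed polarity ledger (+1: H-bond energy, sidechain score, hydrophobic
score, salt bridges, disulfides; −1: unsatisfied count, backbone RMSF,
helix-propensity penalty, capping disruption).  After adjustment, positive
always means predicted stabilizing.  The binary capping flag bypasses the
SD division and enters as 0/−1 (dividing a 0/1 column by its SD would blow
it up out of proportion to the graded metrics).  Zero-variance columns are
dropped with a warning.  The composite is the plain arithmetic mean of the
scaled columns — each (metric × selection) pair stays a separate column —
and mutations are ranked by descending composite, ties broken
lexicographically by mutation identifier.  An optional primary-predictor
column joins the table under the same normalization (polarity −1 for
ddG-style scores where lower is better).

## Structural checks

* **Helices** are assigned once, on frame 1, from backbone hydrogen bonds
  using the Kabsch–Sander electrostatic criterion
  $E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
  kcal/mol with a −0.5 kcal/mol cutoff; α-helices are runs of consecutive
  i→i+4 turns.  Assignment is deterministic.
* **Helix propensity** applies the Pace–Scholtz penalty scale (kJ/mol,
  alanine = 0, proline = 13.22) to positions at least five residues from
  both helix termini; closer positions return 0 so the propensity and
  capping checks never overlap.
* **Capping**: positions within five residues of a helix terminus are
  flagged when the wild-type residue fills a capping role (N-cap:
  Asn/Asp/Ser/Thr/Gly; C-cap: Gly) that the mutant does not preserve.  The
  published capping-motif catalogues are richer than this role table; the
  implemented set is an explicit approximation and replaceable via the
  `motifs` argument.
* **Disulfides** count Cys SG–SG pairs from bond records, falling back to a
  2.3 Å distance criterion on frame 1 when the topology is silent.
* **Salt bridges**: carboxylate oxygens of Asp/Glu strictly closer than 4 Å
  to charged sidechain nitrogens of Lys/Arg (His only when both ring
  nitrogens are protonated in the topology).  Counting is per residue pair
  — a bidentate arginine contact is one bridge, not two — and
  frame-averaged.

## Evaluation toolkit

Rankings are evaluated against measured melting-temperature changes
(ΔTm).  Stabilizing means ΔTm strictly greater than 0 °C; neutral
mutations count as failures (a deliberately conservative convention),
though the threshold is configurable for sensitivity analyses.  The ROC is
built by descending score with tied scores processed as one block (a
diagonal segment) and AUC by the trapezoid rule.  The **stability-weighted
ROC** replaces each positive's uniform TPR step with its share of the total
ΔTm gain, $\Delta T_{m,i} / \sum_j \Delta T_{m,j}$, while negatives keep
uniform FPR steps — rewarding a predictor that puts the *most* stabilizing
mutations first.  When every positive has the same ΔTm the weighted curve
reduces exactly to the plain one.  Trapezoid integration is used for both
curves (block ties make this the natural choice).

For mutation sets where some candidates were never tested, two estimators
bound the truth: `auc_bounds()` flips, for every assumed count *k*, the *k*
best-ranked (upper bound) or worst-ranked (lower bound) untested mutations
to positive, counting the rest negative; `fraction_sweep()` averages the
AUC over uniformly random placements of `round(f·U)` positives among the
`U` untested, seeded and reproducible.

## Machine-learning re-ranking

Given enough labeled mutations, a light model can learn a better weighting
of the scaled metrics than the plain mean.  The harness performs repeated
stratified k-fold cross-validation (defaults: 4 splits, 10 repeats),
pooling out-of-fold scores per repeat and reporting mean plain and weighted
AUC across repeats.  Classifiers (SVC, k-NN, random forest) rank by class
probability; regressors (SVR, ridge, random forest) by predicted ΔTm.
Regression folds are stratified on the stabilizing/non-stabilizing binning
of ΔTm so both fold types balance the rare positive class.  Fold
assignment depends only on the labels, the seed and the fold layout.  Grid
search maximizes the mean of plain and weighted AUC and keeps the first
grid entry on ties.  Estimator internals are delegated to e1071, class,
randomForest and glmnet; the defaults are reasonable starting points, not
claimed optimal.

## Synthetic fixtures

The generator module builds everything the test suite consumes: ideal
peptides from internal coordinates (helix φ = −57°, ψ = −47°; strand
−135°/135°; or custom dihedrals) with idealized extended rotamers and
geometrically placed hydrogens; seeded Gaussian jitter "trajectories" in
which every atom of residue *i* is displaced with per-coordinate standard
deviation $a_i$, so the per-atom RMSF converges to $a_i\sqrt{3}$; toy
systems realizing exact hydrogen-bond, bifurcation, water-bridge and
salt-bridge geometries; and numeric benchmark samples from per-category
log-normal distributions.  These fixtures emulate the *geometry* of real
ensembles, not their physics: there are no correlated motions, no solvent,
no force-field energetics, and sidechain rotamers are not relaxed.  Tests
passing on them demonstrate that the metrics compute what they claim on
controlled inputs — not that the composite score predicts real
thermostability, which requires real MD ensembles and measured ΔTm values.

## Numerical choices and problem sizes

Tolerances and sizes used by the shipped tests are the package's own
choices: analytic toy values are checked essentially exactly (bisection to
~10⁻⁸); the jitter-amplitude recovery uses a 50-residue helix with 2000
frames and a 5 % tolerance (global superposition absorbs six rigid-body
degrees of freedom, a ~2 % deficit at 50 Cα atoms, which the tolerance
accommodates); cross-validation checks use 200 synthetic mutations.  KDE
grids are 512 points; SASA uses 100 sphere points per atom.  Uncapped
termini are modelled plainly (single N-terminal H, no OXT) — fixtures are
test articles, not electrostatically faithful termini.

## Known limitations

* No periodic-boundary handling and no protonation: garbage in, garbage
  out for wrapped or hydrogen-free inputs (both are detected where cheap —
  missing hydrogens and missing bonds error loudly).
* The hydrogen-bond energy is a geometric surrogate without charges,
  π-systems, or cation–π terms.
* The capping-motif table is a coarse role approximation.
* Benchmark curves are only as representative as the ensemble collection
  they were built from; curves built under one force field or timescale
  should not silently normalize another (the CSV surface makes swapping
  explicit).
* Scoring compares ensembles of the *same* protein differing at one
  position; it is not a general ΔΔG predictor.
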