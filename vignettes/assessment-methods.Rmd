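---
title: "Assessing protein complex models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing protein complex models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capriqa)
```

This vignette documents the models, conventions and numerical choices
behind `capriqa`, the way one would document any assessment protocol whose
numbers are meant to be compared across studies: almost every quantity
here (a contact, an interface, an RMSD, an AUC) depends on conventions
that are easy to leave implicit and hard to reproduce afterwards.

## 1. Structures and residue correspondence

A complex is represented as a `complex_structure`: heavy atoms of standard
`ATOM` records, partitioned into a receptor and a ligand chain set (by
docking-benchmark convention the larger and smaller partner). At parse
time hydrogens, waters and `HETATM` records are removed; alternate
locations are resolved to the highest-occupancy copy, ties keeping the
first record in file order. These rules are stated rather than deep:
assessment metrics are heavy-atom metrics, and altloc handling only needs
to be deterministic.

Model-to-native residue correspondence is computed by global sequence
alignment (identity scoring, affine gap penalties) per chain pair, with
chain pairing chosen to maximize the summed alignment score over all
injective assignments (exhaustive; partners here have very few chains).
Correspondence is *never* taken from author residue numbering, because
complex-prediction pipelines renumber freely — in particular the
chain-break convention of adding a residue-index shift of 200 at the chain
junction, which this package's MSA module itself carries as metadata.
Aligned positions with identical amino acids become pairs; mismatches and
unaligned residues are excluded. Chain pairs whose best alignment falls
below 30% identity over aligned columns are treated as a failed
correspondence rather than silently scored. Non-standard residues (MSE
and similar) are translated to their parent amino acid for alignment;
untranslatable residues can only land in the unmatched sets.

Before any metric is computed, both structures are pruned to exactly the
mapped residue pairs, and within each pair atoms are intersected by name.
This mirrors the standard practice of removing predicted residues that are
unresolved in the experimental structure, and it makes every downstream
comparison operate on identical atom sets. Pruning is idempotent and
ordered by the native structure's residue order.

## 2. CAPRI metrics

Three metrics are computed, with the conventions of the community
assessment they come from:

* **fnat** — native contacts are cross-partner residue pairs with any
  heavy-atom distance ≤ 5 Å; fnat is the fraction of those reproduced by
  the model (model contacts are translated to native residue identities
  through the mapping; extra non-native contacts are not penalized). A
  native with zero contacts is an error, not a zero.
* **I-RMSD** — the interface set is defined *on the native only*:
  residues of either partner with any heavy atom within 10 Å of the other
  partner. Backbone atoms (N, CA, C, O) of those residues are superposed
  by least squares and the minimized RMSD is returned. Defining the set on
  the native keeps the atom set fixed across all models of a case.
* **L-RMSD** — the model is superposed on the native by receptor backbone
  atoms alone; the backbone RMSD over ligand residues is then measured
  without further fitting, so it captures the rigid-body placement error
  of the ligand.

The superposition engine is a standard Kabsch solver (SVD of the
coordinate cross-covariance with a determinant correction guaranteeing a
proper rotation). It is validated in the test suite against an
independent quaternion closed-form solution to 10⁻⁹ Å, and the identity
that a pure ligand translation of magnitude *t* yields L-RMSD exactly *t*
holds to the same tolerance.

Classification uses the standard decision table, evaluated top-down so
boundary triples are unambiguous (a triple satisfying both the high and
medium rows is high):

| class      | fnat  | and | RMSD condition                 |
|------------|-------|-----|--------------------------------|
| high       | ≥ 0.5 |     | L-RMSD ≤ 1.0 or I-RMSD ≤ 1.0   |
| medium     | ≥ 0.3 |     | L-RMSD ≤ 5.0 or I-RMSD ≤ 2.0   |
| acceptable | ≥ 0.1 |     | L-RMSD ≤ 10.0 or I-RMSD ≤ 4.0  |
| incorrect  | otherwise                            |

The 5 Å contact cutoff and the 10 Å interface-residue cutoff are the
standard values of this assessment protocol; both are exposed as
arguments. Threshold comparisons are inclusive (`>=` / `<=`). If more
than 10% of native backbone atoms lack a model counterpart after pruning,
`assess()` warns rather than failing: the RMSDs are then computed over the
intersection, which is the only defensible choice, but the user should
know the comparison is partial.

## 3. Interface confidence metrics

Predictors emit per-residue pLDDT (0–100; local accuracy), a pairwise PAE
matrix (Å; expected error in the position of residue *j* when the model is
aligned on residue *i*), and global pTM/ipTM scalars. `capriqa` restricts
the residue-level quantities to the predicted interface:

* **interface pLDDT** — arithmetic mean of pLDDT over residues with any
  cross-chain heavy-atom contact at the cutoff.
* **interface PAE** — mean over contacting cross-chain residue pairs of
  the symmetrized entry (PAE[i,j] + PAE[j,i]) / 2. The PAE matrix is
  asymmetric, and nothing privileges one direction; symmetrizing makes the
  metric independent of which partner is called receptor.

A model with no cross-chain contacts is assigned interface pLDDT 0 and
interface PAE 35 exactly — the "no predicted interface" sentinel values,
placed at the pessimistic end of each scale so such models sort below any
model with a scored interface. The default contact cutoff is 4 Å; the
4–10 Å range is supported (interface sets are monotone in the cutoff by
construction) and in our experiments the choice within that range does not
change discrimination behaviour, only the sentinel frequency: tighter
cutoffs declare more models contact-free.

pLDDT supplied on a 0–1 scale is rescaled to 0–100 (automatically with a
warning, or explicitly via `plddt_scale`). pLDDT can also be taken from
the B-factor column of predictor-written PDB files (per-residue mean).
ipTM, where present, is stored and passed through as a score column; it is
never computed here.

## 4. Complex MSAs and depth

The unpaired complex alignment is block-diagonal: the query row is the
concatenation of the two chain queries; every other chain-A row is padded
with `len(B)` trailing gaps and every chain-B row with `len(A)` leading
gaps. Paired rows (putative interacting orthologs concatenated) can be
appended, or used alone. The 200-residue index shift at the chain
junction is carried as metadata and applied only when emitting
predictor-ready inputs; internal residue keys are never shifted.
Pre-pairing filters (minimum 50% coverage of the query columns, minimum
20% identity to the query) reproduce the filters applied before alignment
pairing in complex-prediction pipelines; the query row is always retained.

Depth is measured as **N~eff~**: the number of clusters after greedy
incremental clustering at 62% identity. Rows are sorted by ungapped
length, longest first; each row joins the first existing cluster whose
*representative* (founding row) shares at least the threshold identity,
with identity defined as matching aligned columns divided by the shorter
ungapped length — the convention of the reference clustering tool this
definition follows. The word-length-4 k-mer prescreen of that tool is an
optimization, not part of the definition, and is omitted; correctness is
pinned by a brute-force greedy oracle in the tests. For paired-MSA depth,
N~eff~ is computed on the paired rows only (each row being the
concatenated pair), via `as_alignment(combined, origin = "paired")`.
Because clustering is greedy, N~eff~ is reported alongside the row count
and is non-increasing as the threshold is lowered.

## 5. Discrimination statistics

Every statistic operates on a `score_table` (one row per model: case,
rank, CAPRI class, score columns) and respects a per-column direction
flag; lower-is-better columns (interface PAE, energies) are oriented at
computation time, never by sign-flipping stored values.

* **Binary AUC** is the Mann–Whitney probability with midrank tie
  handling, identical to exhaustive concordant-pair counting (ties ½) —
  which is how the tests verify it. Constant columns yield 0.5 with a
  warning.
* **Bootstrap CIs** are percentile intervals over 2,000 stratified
  replicates by default (positives and negatives resampled separately,
  preserving group sizes), reproducible under a seed.
* **Multiclass AUC** averages one-vs-rest AUCs over the classes present
  (classes with fewer than 2 models are excluded with a warning), macro by
  default with micro as an option; the CI uses a class-stratified
  bootstrap, percentile or BCa. One design point deserves flagging as a
  reproduction caveat: with a single ordinal score column, the natural
  orientation of a one-vs-rest contrast differs between the top class
  (higher score ⇒ in class) and the bottom class (higher score ⇒ out of
  class). Each per-class AUC is therefore oriented so the class is scored
  as separable (AUC ≥ 0.5). Multiclass AUC tooling differs in exactly
  these conventions, so cross-package comparisons of the multiclass
  number should be made with care; the binary AUCs are convention-free.
* **Optimal cutpoints** maximize sensitivity + specificity over observed
  score values (not midpoints between observations, so reported
  thresholds are achieved values on the original scale); ties break
  toward higher specificity, then the more permissive threshold. The
  objective is ≥ 1 always and equals 2 exactly when the groups are
  separable.
* **Rank-sum tests** are two-sided Wilcoxon/Mann–Whitney: exact
  enumeration when both samples have ≤ 8 observations and no ties, the
  normal approximation with tie and continuity corrections otherwise
  (delegated to `stats::wilcox.test` with those settings). **Pearson**
  correlations use the *t* transform with *n* − 2 degrees of freedom.
  Significance labels follow the conventional bins (ns > .05, \* ≤ .05,
  \*\* ≤ .01, \*\*\* ≤ .001).
* Missing score values drop a row from that column's analysis only.

Top-N success rates (`success_rates`) take, per case, the best CAPRI class
among the top N models ranked by a configurable column (default pTM, the
ranking score of the prediction pipeline this assessment stack serves)
and report the percentage of cases reaching each accuracy level — the
T1/T5 convention.

## 6. The synthetic benchmark generator

The generator exists so that every metric above can be validated
end-to-end with known ground truth and no external data.

**Geometry.** A toy native is two idealized poly-alanine α-helices
(backbone N, CA, C, O built from literature-standard bond lengths and
angles with (φ, ψ, ω) = (−57°, −47°, 180°)), axes parallel, the minimum
inter-chain heavy-atom distance calibrated to a target gap (3.8 Å for
benchmark cases, giving an interface of roughly 10–20 native contacts; a
small 0.05 Å coordinate jitter makes independently seeded toys distinct).
Decoys are rigid-body perturbations of the ligand: rotation about an axis
through its centroid, then translation. For pure translations the L-RMSD
equals the translation magnitude analytically, which pins the metric
implementations to an exact expected value.

**Class sampling.** Candidate perturbations of increasing severity are
assessed and the first reaching each target class is kept — the
assessment, not an assumed magnitude-to-class map, is the arbiter, so the
recorded truth class is the assessed class by construction. The incorrect
class is sampled in two phenotypes seen in real prediction benchmarks: a
flipped binding orientation that keeps interface contacts, and a far
translation with no contacts at all (the phenotype that triggers the
sentinel confidence values).

**Confidence.** Fabricated confidence emulates the empirical association
between interface confidence and accuracy: interface residues (8 Å
definition, on the model) receive pLDDT around 97 / (1 + (I-RMSD/3)³),
non-interface residues around a 92 baseline; cross-chain PAE entries rise
with I-RMSD from a 0.25 Å floor toward 32 Å; pTM decreases linearly with
I-RMSD from 0.92. Noise has a model-level offset component and an
independent per-residue component, both of standard deviation `noise_sd`
(pLDDT units; PAE and pTM noise scaled to their ranges). The model-level
component matters: confidence errors in real predictors are strongly
correlated within a model, and without it, averaging over interface
residues would erase any amount of per-residue noise and score
discrimination would never degrade. At `noise_sd = 0` the construction is
perfectly separable — interface pLDDT orders models strictly by accuracy —
so AUC 1.0 and a cutpoint objective of 2 are exact expectations, and AUC
degrades monotonically in expectation as noise grows.

When the benchmark's score table is assembled, interface pLDDT/PAE are
computed at an 8 Å cutoff, matching the interface definition used by the
confidence fabrication (the package default elsewhere remains 4 Å; within
the supported 4–10 Å range the choice affects only which models are
declared contact-free).

**What the generator does not emulate** — and hence what passing tests do
and do not show: side chains (all contacts are backbone-atom contacts),
chain flexibility and refolding (decoys are rigid), clashes and disorder,
real predictor failure modes, and realistic score overlap structure.
Results on the synthetic benchmark validate the *machinery* (metrics,
classification, statistics) exactly; they say nothing about how well any
particular confidence metric discriminates on real models.

## 7. Problem sizes, tolerances, degenerate inputs

The shipped tests and the acceptance script use toy complexes of 10–28
residues per chain, benchmarks of up to 20 cases × 5 models, 2,000
bootstrap replicates, and 10-seed averages for stochastic properties —
sizes chosen so the whole validation cycle runs in a few minutes while
keeping every oracle exhaustive. Superposition agreement is asserted to
10⁻⁹ Å, brute-force metric agreement to 10⁻⁶ or better, probability
computations to 10⁻¹². Degenerate inputs are errors, not silent values:
fewer than 3 points for a superposition, an empty comparison group, a
constant vector for a correlation, a native with no interface contacts, a
chain pair below the 30% identity floor. Two deliberate exceptions return
defined values: the no-contact confidence sentinels (0 / 35), and the
constant-column AUC (0.5 with a warning), both of which keep batch
pipelines running over heterogeneous model sets.

## 8. Known limitations

* Only binary (two-partner) complexes are supported; partners may have
  multiple chains but chain-pairing search is exhaustive and intended for
  ≤ 4 chains per partner.
* PDB input only (no mmCIF); nucleic-acid chains are not handled.
* fnonnat, DockQ-style composite scores, clash counting and energy-based
  rescoring are out of scope; externally computed score columns can be
  ingested into a `score_table` instead.
* The multiclass AUC convention caveat of section 5.
* The Neff greedy clustering depends on row order (longest-first, as
  specified); it is a depth *estimate*, matching the cited tool's
  behaviour, not an order-free quantity.
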