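---
title: "SAR matrices: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SAR matrices: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

A matched molecular pair (MMP) is a pair of compounds that differ only at a
single site: they can be interconverted by exchanging one substructure.
`sarmatrix` applies the MMP formalism at two levels to organize a compound
collection into SAR matrices:

1. **Compound MMPs.** Every compound is fragmented by systematic deletion
   of one, two, or three exocyclic single bonds between heavy atoms. Each
   cut yields a *key* (the core, one connected fragment carrying all
   attachment points) and *values* (the substituents, one per attachment
   point). All compounds sharing a key form a matched molecular series
   (MMS): an analog series differing only at the cut site(s).
2. **Core MMPs.** The cores themselves are single-cut fragmented. Cores
   sharing a second-level sub-key differ by one structural modification at
   a single site — they are *structurally analogous*. The series built on
   such cores are grouped (A_MMS), and each group becomes one matrix.

In the matrix, rows are the analogous cores, columns the union of
substituent combinations over the member series, and every (row, column)
pair is exactly one cell. Cells occupied by data-set compounds are *real*
(color-coded by potency on a red–yellow–green spectrum); the remaining
combinations are *virtual compounds* (VCs), generated structures that are
immediate, synthetically plausible design suggestions. Single-, dual-, and
triple-cut matrices are generated separately.

## Matrix statistics

For a column populated with real compounds in `n_col` of `#rows` rows, the
row overlap is

    RO = (n_col - 1) / (#rows - 1)

so RO is 0 when a column is unique to one series and 1 when every series
explored that substituent. Matrix overlap is the mean of RO over columns;
matrix coverage is `C = n_matrix / (#rows * #columns)`, the fraction of
cells that are real. Both are exact rational evaluations, tested at their
analytic boundary values.

## SAR analytics

* **Analog pairs** are unordered pairs of annotated real cells sharing a
  row or a column — within-matrix MMPs.
* **Discontinuity** is the mean absolute pKi difference over analog pairs.
  The underlying literature names discontinuity-based ranking without
  printing a functional form; the mean pairwise difference is the simplest
  faithful reading, is invariant under row/column permutation and potency
  translation, and is the package's declared scoring function (continuity
  is its negation for ranking).
* **Activity cliffs** are analog pairs with ΔpKi at or above 2 log units
  (100-fold), the prevailing convention; the threshold is inclusive and
  configurable.
* **SAR transfer** between two rows requires at least 3 columns annotated
  in both and Spearman rank correlation ≥ 0.8 of the paired potencies.
  Rank correlation is used deliberately: parallel potency *progression* is
  an ordinal notion, not a linear one.
* **Preferred cores** are rows whose annotated cells all reach a potency
  cut, with at least two annotated cells as support.

## Neighborhood-based potency prediction

A neighborhood (NBH) of a virtual cell X consists of three real annotated
cells: E in X's column (same substituent), G in X's row (same core), and D
combining E's core with G's substituent. Under Free–Wilson additivity of
logarithmic core and substituent contributions,

    pKi(X) = pKi(E) + pKi(G) - pKi(D)

exactly. Qualifying NBHs are collected across all matrices containing the
same virtual structure and deduplicated by the unordered (E, G, D)
compound triple — the same triple recurs in overlapping matrices and would
otherwise inflate the neighborhood count and artificially shrink the
prediction spread. Per-VC predictions are summarized by mean and sample
standard deviation.

Candidate prioritization applies the applicability domain: at least 3
NBHs (so consistency can be assessed), prediction SD at most 0.5 pKi
units, and at least one source matrix with discontinuity at most 1.0. The
minimum NBH count follows the method literature; the SD and continuity
limits are package defaults chosen at the scale of the noise studies below
(an SD cap of 0.5 admits predictions whose spread is well under twice a
typical 0.3-log assay noise) and are exposed as arguments. Compounds near
activity cliffs fall outside additivity; for those the package emits
guilt-by-association candidates — virtual cells sharing a row or column
with the more potent cliff partner — deliberately without a numeric
prediction.

If every observed pKi carries i.i.d. Gaussian noise with SD σ, the error
of a single NBH prediction against the held-out observed value is
ε_E + ε_G − ε_D − ε_X with variance 4σ²; the package's validation checks
that the empirical RMSE over pooled NBHs matches 2σ.

## Multi-target matrices

Compound series matrices (CSMs) share the SARM skeleton but annotate each
real cell with the set of targets the compound is active against; the
promiscuity degree is the size of that set, rendered white to dark blue.
"Active against" defaults to the presence of any annotation; an optional
pKi threshold restricts it. Deconvolution produces one single-target
matrix per target with the identical skeleton; real cells without an
annotation for that target stay real but unannotated (gray), and the union
of deconvoluted annotations reconstructs the profiles exactly — a
conservation law the tests assert.

## The synthetic library generator

The generator builds combinatorial libraries with known ground truth:
compounds `R–scaffold–V` from hand-curated two-attachment ring scaffolds,
a small variant group V defining the analogous cores, and a substituent R
defining the columns. Because the scaffolds are pure ring systems, the
only exocyclic bonds are the two attachment bonds plus bonds inside R, so
the intended core/substituent decomposition is always among the
enumerated cuts, and removing V is a qualifying second-level cut — every
scaffold's variants land in one A_MMS.

Ground-truth potencies are additive at the level of atomic composition:
one uniform draw per scaffold (range `core_effects`, default ±0.4 pKi)
plus per-element atomic weights (range `substituent_effects` divided by
the largest substituent size, keeping total substituent contributions
within ±0.4). This is a deliberate strengthening of naive per-core /
per-substituent draws: systematic fragmentation also produces *incidental*
decompositions (e.g. cutting inside an alkyl chain), and with independent
per-fragment effects those matrices would violate additivity even though
the generator is nominally "additive". With composition-level additivity,
any partition of a molecule partitions the atom sum, so **every** matrix
the pipeline builds carries an exactly additive surface and the noise-free
exact-recovery property holds for every neighborhood, as it should.

Defaults define the validation conditions used throughout: 3 scaffolds ×
4 core variants × 6 substituents (72 compounds), baseline pKi μ = 6.5,
15% of cells held out (they surface as virtual cells with recorded true
and observed values), no observation noise. Seeded activity cliffs add
δ = 3.0 to chosen compounds; since analog-pair differences from the
effect ranges are bounded by 0.8, seeded pairs always exceed the 2-log
cliff threshold, making 100% recovery a designed property rather than a
statistical one. A multi-target variant draws independent effect sets per
target and annotates each compound on a random target subset (per-target
inclusion probability 0.7 by default, at least one target each).

What the generator does *not* emulate: realistic medicinal-chemistry
property distributions, correlated assay errors, stereochemistry, and
activity landscapes that deviate from additivity in structured ways.
Passing tests demonstrate the mechanics of fragmentation, matrix
assembly, and prediction — not predictive performance on real SAR data.

## Numerical and structural choices

* **Canonical forms.** All structure identity is string equality of Open
  Babel canonical SMILES. Attachment points are isotope-labelled dummy
  atoms `[1*]`–`[3*]` (first level) and `[9*]` (second-level cut site);
  the `[*:n]` map notation is accepted on input. Canonicalization of a
  multi-point key minimizes the canonical string over all attachment-label
  permutations, and the chosen permutation re-orders the value tuple, so
  label assignment is input-order independent. Ties occur only for keys
  symmetric under a label swap; the first minimizing permutation is taken,
  and because tied permutations correspond to automorphisms of the key,
  cell structures are unaffected.
* **Salts.** Multi-fragment inputs are reduced to the largest organic
  fragment with a warning; fragmentation assumes one connected molecule.
* **Stereochemistry.** Compound canonicalization preserves stereo
  descriptors present in the input, but fragmentation operates on the
  constitutional graph: configurations at or near cut sites are not
  carried through keys and values. Libraries used for validation are
  achiral; with stereo-annotated input, distinct stereoisomers remain
  distinct compounds but may collide on one matrix cell, in which case the
  first is kept with a warning.
* **Hydrogens** are never cut and never counted as heavy atoms.
* **Constraints.** Defaults: substituents ≤ 13 heavy atoms, key ≥ 5 heavy
  atoms and at least half the molecule. The underlying publications leave
  these open and matrix counts on real data depend on them, so they are
  arguments everywhere, not constants.
* **Symmetric scaffolds.** When a core's two substitution sites are
  equivalent by symmetry (e.g. para-phenylene), the substituent-side and
  variant-side cut orientations share one sub-key and the resulting matrix
  mixes both orientations — rows such as ring–F and ring–ethyl are
  genuinely analogous cores under the single-site definition, and one
  compound may occupy two cells of the same matrix. This is a faithful
  consequence of the formalism; fixtures that need a clean grid use an
  asymmetric (pyridine) scaffold.
* **Degenerate inputs.** Molecules with no cuttable bond produce an empty
  fragmentation list, not an error; matrices below the population filters
  (2 rows, 3 real cells by default) are dropped; matrices without analog
  pairs have undefined discontinuity and are excluded from ranking with a
  notice.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle at desk
scale: fragmentation against exhaustive subset enumeration with
breadth-first connectivity on 200 generated molecules of up to 30 heavy
atoms (all three cut levels, with 100% round-trip reassembly); series
detection against O(n²) pairwise MMP detection on ten libraries of at
most 50 compounds; noise-free exact recovery of every held-out cell;
noise scaling over twelve replicate libraries pooling more than 2000
neighborhood predictions; seeded-cliff recovery; and exact CSM
conservation. Overlap and coverage are checked at their printed boundary
values on constructed matrices. These sizes were chosen so the whole
suite runs in minutes on a single core while each property is exercised
far beyond its failure modes.

## Known limitations

* Ring bonds are never cut, and cores match by exact canonical identity —
  no fuzzy or maximum-common-substructure matching.
* Matrix counts and virtual-compound counts on real data sets depend
  strongly on the fragmentation constraints; published full-scale counts
  are not reproducible without the same compound sets and constraint
  settings.
* The discontinuity score is one of several defensible definitions; rank
  orders under alternative definitions may differ.
* HTML export shows structure strings, not depictions.
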