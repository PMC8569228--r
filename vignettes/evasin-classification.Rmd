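---
title: "Classifying evasin-like proteins: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying evasin-like proteins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evasinclass)
```

## The procedure

Evasins are tick salivary proteins that neutralize host chemokines; class A
binds CC-chemokines, class B binds CXC-chemokines, and each class conserves
a characteristic cysteine framework. Candidate evasin-like proteins from
salivary transcriptomes are classified by where they fall in a
distance-based phylogeny of mature protein sequences, rooted at its
midpoint: the two clades descending from the root define the top-level
classes, and one further split defines subclades. This vignette documents
the models, parameters and numerical choices behind each stage, and what
the synthetic-data tests do and do not demonstrate.

## Mature-protein derivation

The protein start is the first methionine of each record — the rule is
applied literally, so an upstream Met in a 5'-UTR-derived prefix wins over
any downstream "true" start; records with no Met at all are dropped with
their own reason (`no_met`), since no stated rule can place their start.
Signal-peptide cleavage is a pluggable contract: given the Met-initiated
protein, a provider returns the offset of the first mature residue or "no
signal". Two providers ship:

* **table-backed** — positions supplied by the user (e.g. exported from a
  neural-network signal-peptide predictor). Positions are 1-based in the
  raw precursor; records absent from the table count as signal-free. No
  predictor is re-implemented here: the pipeline only ever consumes a
  cleavage position.
* **heuristic** — a signal peptide is called when the residues after the
  initiator Met form an uninterrupted hydrophobic run (A/I/L/V/F/M/W) of at
  least 8 residues (capped at a 40-residue window); the mature protein
  starts right after the run. This is a deliberately simple, documented
  model matched to the synthetic generator, not a general predictor.

Records are then filtered: no signal peptide, or a `*` anywhere in the
*mature* sequence, drops the record. A stop codon upstream of the mature
start does not — the filter is defined on the predicted mature protein
only. Filtering is a partition (every record kept or dropped with exactly
one reason) and idempotent.

## Homology screen

Every candidate mature sequence is aligned locally (Smith–Waterman, affine
gaps) against each characterized-evasin query. Defaults: BLOSUM62, gap
open 11, gap extend 1 (a gap of length L costs 11 + L). Significance uses
the Karlin–Altschul form

$$E = K \, m \, n \, e^{-\lambda S}$$

with K = 0.041 and λ = 0.267 (natural-log units, typical of gapped BLOSUM62
statistics), m and n the actual lengths of the compared pair unless an
effective search space is configured. A candidate is kept iff its best
E-value is **strictly** below 10⁻⁴. These statistics are a desk-scale
stand-in for a full BLAST search: they preserve the decision rule
(E < 10⁻⁴ against the query set) but not BLAST's composition-based score
adjustments, so keep/drop boundaries near the threshold on real data can
differ from a production BLAST run. "Distinct sequences" is read minimally:
byte-identical mature sequences collapse to the lexicographically smallest
id.

## Motif profiling

The two frameworks are expressed as PROSITE-style patterns — anchors `C`
separated by bounded gaps `x(min,max)`:

* Cys6 (class B knottin): `C-x(3)-C-x(6,10)-C-x(3,6)-C-x(1)-C-x(10,11)-C`,
  span 29–37 residues;
* Cys8 (class A1): `C-x(14,17)-C-x(3)-C-x(11,16)-C-x(17,20)-C-x(4)-C-x(4,5)-C-x(8)-C`,
  span 69–81 residues.

Design choices: `x` matches any residue **including cysteine** (standard
PROSITE semantics — extra cysteines in a gap never block a match, since the
cysteine count is reported separately); the pattern is unanchored and the
full mature sequence is scanned, as nothing restricts the framework to the
N-terminus; the scanner enumerates *every* valid anchor tuple (leftmost
start first, then increasing gap widths), so its output is directly
comparable to an exhaustive enumeration oracle, and "presence" is simply a
non-empty hit list. Whitespace inside patterns is ignored, which also
absorbs typographical spaces that appear in some printed motif
descriptions.

## Alignment

Progressive alignment in the ClustalW mould: (i) all pairwise global
alignments (Gotoh affine-gap DP; defaults BLOSUM62, gap open 10, gap
extend 0.5) give identity distances 1 − matches/columns; (ii) a UPGMA guide
tree over those distances fixes the merge order, ties broken by the
lexicographically smallest pair of cluster representatives; (iii) profiles
merge bottom-up with profile–profile Gotoh DP under average-linkage column
scores (mean substitution score over residue pairs; residue-vs-gap pairs
contribute 0), so gaps, once inserted, are never removed. DP ties prefer an
aligned pair over a gap, then a gap in the first profile, making the result
deterministic for a fixed input order; input-order *independence* is not
promised — progressive alignment is inherently order-sensitive through
tie-breaking. There is no iterative refinement. The substitution matrix is
a config knob (BLOSUM and PAM families as shipped with Biostrings);
downstream identity-based distances are insensitive to modest aligner
differences, which is why matrix choice is logged rather than fixed.

## Distances, tree, support, root

* **Distance**: for each row pair, compared columns are those where both
  rows are non-gap (pairwise deletion; complete deletion available), and
  `d = sqrt(1 − matches/compared)`. Pairs with no comparable columns get
  d = 1 with a warning rather than an error, so one pathological pair
  cannot abort a large run.
* **Neighbour joining**: Saitou–Nei agglomeration on Q(i,j) =
  (r−2)·d(i,j) − R_i − R_j; ties broken by the smallest index pair in the
  current matrix order. Negative branch-length estimates (numerically
  legitimate in NJ) are clamped to zero with the deficit moved to the
  sibling edge, preserving the pair's total. On additive matrices the tree
  reproduces the input path lengths to machine precision.
* **Bootstrap**: replicates resample alignment columns with replacement
  (same count), recompute distance + NJ, and each internal edge of the
  reference tree is scored by the fraction of replicates containing the
  same leaf bipartition (matching ignores branch lengths and rooting).
  100 replicates by default; the resampling stream is seeded, so supports
  are reproducible.
* **Midpoint root**: the root is the midpoint of the longest leaf-to-leaf
  path, which minimizes the maximum root-to-leaf depth; ties among equally
  long paths break on the lexicographically smallest leaf pair, and a
  midpoint landing exactly on a node yields a zero-length root edge. An
  all-zero-length tree is an error (the midpoint is undefined; the message
  points at the distance matrix). Outgroup rooting is deliberately absent:
  no appropriate outgroup exists for this family.

## Classification

Genus determines lineage through an explicit table (Ixodes → Prostriate;
Amblyomma, Dermacentor, Hyalomma, Rhipicephalus → Metastriate), extensible
by the user; an unmapped genus is an error, never a silent default. The two
clades under the root are named by **lineage majority** — the
Metastriate-majority clade is A1 (or B1), the other A2 (B2) — rather than
by size, because the class labels are semantically anchored to lineage. If
both clades share a majority, the larger one takes the lower label; this
convention for the B1/B2 naming is a documented package choice, as no
published rule fixes it. Scheme A warns when a clade is not lineage-pure
(class A separates perfectly by lineage in published data); scheme B
permits mixed clades silently. Purity (the majority-lineage fraction) is
always reported, and bootstrap support is attached to the class-defining
edges but never gates the classification. Fig-4-style binding summaries
count **distinct chemokines per group** (not evasin–chemokine pairs); pair
counting would be the one-line change of dropping a `distinct()` step.

## The synthetic generator

The generator emulates exactly the statistical structure the analysis
relies on, with defaults acting as the study conditions:

* two lineages of 10 sequences each; mature length 90, signal length 20;
* expected substitutions per non-anchor site: 0.05 within a lineage, 0.40
  between the lineage ancestors (the within < between gap is what makes the
  planted partition recoverable, and is enforced at config time). The
  published analysis does not quantify divergence within or between
  classes, so these rates are calibration choices: 0.40 between lineages
  leaves cross-lineage homology easily detectable by the screen while
  giving NJ an unambiguous split; 0.05 within keeps realistic within-clade
  diversity;
* a Cys8 framework planted in the Metastriate-like lineage, none in the
  Prostriate-like lineage (mirroring the A1/A2 contrast). Anchor cysteines
  are immutable during evolution — the classes conserve their cysteine
  frameworks — and all non-anchor positions draw from the 19-letter
  non-cysteine alphabet, so spurious framework matches are essentially
  impossible and motif soundness is testable;
* signal peptides are `M` followed by residues drawn from the hydrophobic
  set {A,I,L,V,F,M,W}, and the first mature residue is pinned to a polar
  residue and held immutable. This makes the heuristic cleavage provider
  recover the true cleavage site exactly — generator and provider share one
  signal model by design, which is precisely what makes the round-trip a
  meaningful contract test and *not* evidence about real signal peptides;
* one decoy of each type: no signal peptide (Met followed directly by a
  polar residue), an internal stop in the mature region, and an unrelated
  random sequence that passes ingest but fails the homology screen.

The two lineage ancestors are emitted as the query set standing in for
characterized evasins. What the generator does **not** emulate: indels
(substitution-only evolution), codon-level processes, rate heterogeneity
across sites or lineages, compositional bias, and real signal-peptide
diversity. Passing the planted-structure tests therefore shows the
pipeline's machinery is correct and internally consistent — not that the
heuristic provider or the E-value stand-in would reproduce
production-tool decisions on real transcriptomes.

## Determinism and problem sizes

Every stochastic step flows from one top-level seed through per-stage
derived seeds, and seeded code restores the caller's RNG state. Run
manifests list every artifact with MD5 checksums and carry no timestamp, so
identical config + seed gives byte-identical output trees — the property
the determinism tests assert.

The test suite validates algorithms against independent oracles at sizes
where brute force is exact: local and global alignment vs Gotoh DP oracles
on hundreds of random pairs up to 30 residues; the motif scanner vs
exhaustive anchor-tuple enumeration on 500 random 40-mers; NJ vs random
additive matrices of 5–12 taxa (path-length residual < 10⁻⁹) and the
three-taxon closed form; midpoint rooting vs a discretized
every-edge-point oracle on 100 random trees. Planted-structure recovery
runs the full pipeline (100 bootstrap replicates) across 20 seeds at the
default conditions; these sizes were chosen so the whole suite validates
every contract in a few minutes while staying at scales where the oracles
are exhaustive.

## Known limitations

* The screen's fixed (K, λ) are not recomputed per matrix/gap setting; a
  user switching matrices should supply matching statistics.
* Progressive alignment has no sequence weighting or position-specific gap
  penalties, so dense clades can dominate profile columns.
* Identity distances saturate for deeply diverged pairs (d → 1); no
  model-based correction is applied, matching the published procedure.
* The deposited class A/B record lists are not redistributable with the
  package; the acceptance test that re-derives the published clade sizes
  from them runs (and fails) until those files are placed under
  `inst/extdata/`.
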