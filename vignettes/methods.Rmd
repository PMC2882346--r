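---
title: "Detecting paralog-diagnostic divergent residues: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting paralog-diagnostic divergent residues: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paradiv)
```

# The analysis

`paradiv` addresses one recurring question in molecular evolution: after a
gene duplication, which residues distinguish the two paralogous families
consistently across species, and do those residues concentrate on one
region of the shared fold? The motivating system is the fission-yeast
Tup11/Tup12 co-repressor pair, whose C-terminal WD40 domain folds into a
seven-bladed β-propeller; the machinery is generic for any two paralog
groups with an outgroup and an optional reference structure.

The pipeline has four stages: (i) alignment and phylogeny, (ii) the
divergent-residue rule, (iii) structure mapping with a clustering test,
and (iv) a simulator providing ground truth. Each is described below
together with the design decisions that were genuinely open.

# Alignment and phylogeny

## Pairwise alignment

Global (Needleman–Wunsch) alignment with the Gotoh affine-gap recursion,
maximizing the summed substitution score minus gap costs, where a gap of
length $L$ costs $g_o + (L-1)\,g_e$. Defaults are BLOSUM62 with
$g_o = 10$, the classic "gap penalty of 10" convention for protein work,
and $g_e = 0.5$, the ClustalW-style extension cost. Only $g_o$ is fixed
by convention; the extension value is a choice, exposed in
`alignment_params()`, made so that long indels are charged mostly once
rather than per residue. The dynamic program is written in C++ over a
precomputed position-by-position score matrix, which lets the same kernel
align single sequences and alignment profiles.

Traceback ties are broken by a fixed preference order — substitution,
then gap in the second input, then gap in the first — purely for
determinism; tied alignments have equal score by definition. The score
contract is verified against exhaustive enumeration of every monotone
alignment path for short sequences (200 random pairs of length ≤ 6 in the
test suite), which is the only regime where enumeration is feasible and
is sufficient because the recursion is length-independent.

## Percent identity

$100 \times$ (columns with identical non-gap residues) / (columns where
*both* rows are non-gap). The denominator choice matters: counting
columns where either row is gapped would make identity depend on terminal
gap placement, which is arbitrary for domains of unequal length. The
chosen definition is symmetric and ignores indels entirely; it is applied
both to the domain-wise cross-comparison (`domain_identity_matrix()`)
and, via $d = 1 - \mathrm{pid}/100$, to the distances feeding the tree.
An alignment with zero comparable columns has no defined identity; the
function returns 0 with a warning rather than NaN so that distance
matrices stay finite.

## Domain partitions

`default_domain_partitions()` carries the published N / middle /
C-terminal boundaries of the seven Tup proteins (e.g. the
*S. cerevisiae* reference: 1–89, 90–317, 318–713). Partitions are
validated to be contiguous, ordered, and to start at residue 1; the last
range must end at the sequence length, which catches off-by-one errors in
user-supplied tables early.

## Neighbor joining

Saitou–Nei NJ, selecting at each step the pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$. Three choices
were open:

* **Distance model.** The default transform is $d = 1 - f$ with $f$ the
  fractional identity, with a Poisson correction $d = -\ln f$ selectable.
  No correction is the default because the downstream use is clade
  membership, not branch-length inference, and the uncorrected transform
  is defined at 0% identity.
* **Tie-breaking.** Among equal-$Q$ pairs the lexicographically smallest
  active-index pair is joined. Any rule would do; this one makes trees a
  pure function of the input matrix.
* **Negative branches.** NJ's branch-length estimator can go negative on
  non-additive inputs; estimates are clamped to zero with a message, the
  convention most tree software follows, and flagged on the returned
  object.

The final three clusters are resolved by the closed form
$\ell_a = (d_{ab} + d_{ac} - d_{bc})/2$. Correctness is tested by
recovering the generating topology of random additive trees (4–8 leaves),
where NJ is provably exact, rather than against another implementation.

## Progressive multiple alignment

Profiles are merged bottom-up along the NJ guide tree, midpoint-rooted to
fix the merge order. The profile–profile column score is the mean over
all cross-row pairs: substitution score for residue–residue, $-g_e$ for
gap–residue, 0 for gap–gap; merging never removes an existing gap
("once a gap, always a gap"). This is deliberately the plain textbook
scheme: sequence weighting, position-specific penalties, and deferred
divergent sequences — the full ClustalW heuristics — are out of scope,
and the package's guarantees about the MSA are correspondingly modest
(degenerate-case identities and induced-pair consistency, not optimality).
One practical consequence, visible with planted data, is that runs of
adjacent divergent sites can legitimately align shifted-with-gaps instead
of column-to-column when the gap cost is cheaper than the mismatches.

# The divergent-residue rule

A column of the MSA is **group-diagnostic** when

1. all criterion-species rows of group A carry one identical non-gap
   residue $r_a$;
2. likewise group B gives $r_b$;
3. $r_a \neq r_b$; and
4. the pair is significant: $\mathrm{BLOSUM62}(r_a, r_b) < 0$ *or* the
   residues carry opposite net charge.

Charges are fixed as D, E $= -1$; K, R $= +1$; everything else 0.
Histidine is the debatable entry — its charge is pH-dependent — and is
conservatively neutral by default, with `h_positive = TRUE` available.
Identical residues are outside the predicate's domain and raise an error
rather than returning `FALSE`; this keeps "not significant" meaning
"compared and found similar".

Three edge rules: columns where any criterion row is gapped are *skipped*
(the rule compares residues, not indels); an `X` in a criterion row also
disqualifies the column, since identity cannot be certified against an
ambiguity code; and non-criterion rows are displayed but never consulted,
so adding a species to the alignment cannot change the site list. The
criterion-species default in `group_spec()` is the set of species present
in both groups; an analysis like the Tup case, where the criterion is
deliberately restricted to the two species with functionally validated
paralogs, passes them explicitly.

Reported sites are polarized against the outgroup row:
`A_matches_outgroup`, `B_matches_outgroup`, `both_differ`, or
`unclassified` when the outgroup is gapped. The scan is verified against
an independently coded brute-force column checker on 200 random toy
alignments per run.

# Structure mapping and the clustering test

## Mapping

The reference row's $k$-th non-gap position maps to author residue number
$\mathrm{ref\_start} + k - 1$; reference-gap columns are unmapped. Author
numbering is taken verbatim from the coordinate records — no renumbering —
so site tables read directly against the literature. Only CA atoms are
kept (one point per residue suffices for all downstream geometry; parsing
is delegated to `bio3d`), the first-listed alternate conformer is used,
and non-standard residues are an error. Residues expected in the domain
span but absent from the coordinates are carried as *disordered*: they
appear in site tables and blade counts (flagged), are omitted from viewer
attribute files, and are excluded from spatial statistics, which need
coordinates.

## Blade annotation

Blade/strand boundaries are a user-supplied TSV, not package constants:
real boundaries must be curated from a crystal structure.
`default_blade_annotation()` is the annotation of the package's toy
propeller — seven blades, matching the WD40 fold — and is intended for
testing and as a template.

## Permutation test

Null model: the observed number of sites placed uniformly at random
without replacement among eligible residues — all annotated residues for
the `max_blade_count` statistic (upper tail), all resolved residues for
`mean_pairwise_ca_distance` (lower tail). Eligibility deliberately
excludes nothing by conservation: testing against the all-residue null is
conservative, and a restricted eligible set can be supplied where a
specific surface should be excluded.

Numerical conventions: when $\binom{|\mathrm{eligible}|}{|\mathrm{sites}|}
\le 10^5$ the null is enumerated exhaustively and $p$ is the exact
proportion of subsets at least as extreme; otherwise Monte-Carlo sampling
with the add-one correction $p = (1 + \#\mathrm{extreme})/(1 + B)$, which
cannot return 0 and is exactly discrete-uniform under the null.
Comparisons against "as extreme" use a $10^{-12}$ slack so that
floating-point copies of the observed statistic count as ties. Results
carry their seed and are bit-reproducible; the caller's RNG state is
never disturbed. Calibration is checked empirically in the tests: 500
null datasets × 200 permutations on the toy structure, with the p-value
distribution tested for uniformity (Kolmogorov–Smirnov at
$\alpha = 0.01$) — the continuous distance statistic is used there
because the blade-count statistic is heavily tied and its p-values are
uniform only on a coarse lattice.

# The simulator

`simulate_paralog_families()` emulates exactly the structure the
detection rule assumes: an ancestor duplicated into two clades over a
**star** species tree (independent lineages — the real three-species
topology is irrelevant to a column-wise criterion), $k$ diagnostic sites
where clade B carries a replacement satisfying the requested mode
(`blosum_negative`, `opposite_charge`, or `both`), per-lineage neutral
substitutions at non-diagnostic sites with probability $\theta$, and
with probability $\varepsilon$ per diagnostic site one corrupted
criterion row. Defaults — 3 species, 2 criterion species, $L = 400$
(a WD40-domain scale), $k = 10$, $\theta = 0.05$, $\varepsilon = 0$, an
outgroup included — were fixed once as the study-like condition.

Two generator choices deserve a note:

* **Ancestral residues at diagnostic sites.** A uniformly drawn ancestral
  residue admits no opposite-charge partner whenever it is neutral, so
  charge-involving modes would fail on most sites under naive rejection
  sampling. The site's ancestral residue is therefore drawn jointly with
  its replacement, uniformly over the ordered pairs satisfying the mode;
  clade A and the outgroup keep that ancestral state, which also gives
  the outgroup classification a defined expectation
  (`A_matches_outgroup`).
* **Indel-free output.** Truth labels are column positions; indels would
  make them ambiguous. Gap handling is exercised separately by hand-built
  alignment fixtures.

What the simulator does *not* emulate: indels, rate heterogeneity across
sites, substitution-matrix-biased neutral drift (replacements are uniform
over the 19 alternatives), and non-star species topologies. Passing the
recovery tests therefore demonstrates the correctness of the detection
logic and its noise response, not performance on realistically evolved
sequences — on real data the progressive aligner, not the detector, is
the accuracy-limiting stage.

`make_toy_structure()` places blades as tight local clusters (spread
≈ 3 Å) on a 50 Å circle, so inter-blade centroid distances (≈ 43 Å)
dominate intra-blade spread by more than an order of magnitude and
within-blade site sets are geometrically detectable by construction. The
layout is deterministic; disorder is emulated by omitting requested spans
from the coordinate records.

# Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and restores the caller's
RNG state. Pipeline outputs begin with a comment header recording the
package version, the config file's md5 hash, and the seed; newline-level
determinism of the full pipeline is itself a tested property. Aligned
FASTA uses `;` comment lines for its header so the files remain valid
FASTA.

The test and acceptance runs use deliberately compact problem sizes,
chosen as the smallest scales at which each property is meaningfully
exercised: 200 random pairs (length ≤ 6) for aligner optimality, 100
random additive trees (4–8 leaves) for NJ recovery, 200 random toy
alignments (6 rows × 50 columns) for the oracle-equivalence check, 50
simulated families per corruption level for the recall curve, and
500 × 200 permutations for null calibration.

# Known limitations

* The progressive MSA implements no sequence weighting or
  position-specific gap penalties; highly divergent or repeat-rich
  families may misalign, and divergent-site coordinates are only as good
  as the alignment.
* The divergence rule is a deterministic filter, not a statistical test;
  it assigns no per-site significance and makes no correction for the
  number of columns scanned.
* Blade assignment uses strand ranges only; sites in loops between
  strands are counted "unassigned" rather than attributed to the nearest
  blade.
* mmCIF files, multi-model NMR structures, and B-factor/occupancy-aware
  conformer selection are unsupported; coordinates beyond one CA per
  residue are discarded.
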