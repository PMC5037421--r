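---
title: "Methods: progressive protein MSA with LCS similarities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: progressive protein MSA with LCS similarities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsmsa)
```

This vignette documents the model behind `lcsmsa`, the parameters that
matter, the numerical and design choices that were genuinely open, and
what the test suite does and does not demonstrate.

## The pipeline and its assumptions

`msa_align()` runs four stages: (I) all-pairs similarities, (II) guide
tree, (III) progressive profile merging, (IV) iterative refinement.  The
underlying assumption of every progressive aligner applies here too:
merges are greedy and never revisited, so the guide tree's merge order —
not any global objective — determines which pairwise decisions are
frozen early.  Refinement (stage IV) partially compensates.

### Stage I — LCS/indel similarity

For sequences $A$, $B$ the longest common subsequence length
$\mathrm{LCS}(A,B)$ counts the maximal number of perfectly matching
columns; the indel distance is
$\mathrm{indel}(A,B) = |A| + |B| - 2\,\mathrm{LCS}(A,B)$, the number of
single-symbol insertions/deletions transforming one sequence into the
other.  Similarity and clustering distance are
$\mathrm{sim} = \mathrm{LCS}/\mathrm{indel}$ and
$\mathrm{dist} = \mathrm{indel}/\mathrm{LCS}$ (monotone inverses;
single linkage conventionally consumes dissimilarities, and inverting
preserves the induced tree).  Two degenerate cases are not covered by
the formulas and are fixed here by convention: identical sequences get
$\mathrm{dist} = 0$, and disjoint sequences
($\mathrm{LCS} = 0$) get the finite sentinel $|A|+|B|+1$, strictly
larger than any attainable distance, so the clustering always sees
finite, ordered values.

The bit-parallel kernel packs 64 DP cells per machine word
(`V = (V + (V & M)) | (V − (V & M))` row update with carry/borrow
propagation across words, LCS = bits − popcount).  It is an
implementation detail constrained only by exact agreement with the
plain DP recurrence, which the suite checks on more than $10^3$ random
pairs including word-boundary lengths.

### Stage II — guide trees

SLINK processes distance rows $i = 1..k$ once, maintaining the
pointer-representation arrays $(\pi, \lambda)$ in $O(k)$ memory; the
suite feeds it a counting stream to assert single-pass consumption.
The pointer representation is not itself a binary tree; it is
converted by processing points in ascending $(\lambda, \text{index})$
order, so exact ties merge the smaller sequence index first — a
deterministic choice the pointer algorithm leaves open.  Merge heights
are recorded but stage III consumes only the merge order.

UPGMA is provided for comparison as a naive $O(k^3)$-time,
$O(k^2)$-memory routine (adequate at the scales where UPGMA is
preferable at all) and is cross-checked against
`stats::hclust(..., "average")`; chained trees need no distances and
are the fastest, most imbalanced baseline.  Newick import (via `ape`)
requires a rooted, strictly binary tree whose labels biject onto the
sanitized sequence ids; branch lengths are ignored because only the
merge order matters downstream.

Tree statistics: the Sackin index is the sum of leaf depths with root
depth 0 (normalised: divided by the leaf count $k$); the covering
fraction of a leaf subset is the leaf count of the smallest clade
containing the subset divided by $k$, with a Monte-Carlo baseline
averaging over uniformly drawn subsets of the same cardinality.

### Stage III — gapped profiles and the affine DP

A member row is stored as residue codes plus `no_gaps[j]`, the number
of gaps immediately before residue `j` (a guard slot counts trailing
gaps), and a heap-ordered prefix-sum tree `dps` over the per-slot
column counts (`dps[i] = dps[2i] + dps[2i+1]`, leaves covering two
slots, root = realized width).  Columns are 0-based; insertion "at
col" means before the column currently at that index.  Whether the
guard participates in the prefix-sum tree was unspecified in the
design; here the guard's gap count is part of the root sum, so the
root always equals the profile width.

Profiles add per-column occurrence counters over 29 symbols (25
residue codes — the 20 standard amino acids plus B, Z, X, U, O; other
letters map to X with a warning — and the four gap types).  Counters
store gap *types*, not a single gap code, because the correction rules
below retype existing gaps; a consistency oracle (full recount from
realized rows) is asserted after randomized insertion sequences.

The DP has three states (match, gap column in X, gap column in Y) and
maximizes the summed pairwise score of the merged profile.
Within-profile pairs are constants with respect to the matching and are
included in the reported score.  Match costs come from the counter
quadratic form $c_x^\top P\, c_y$ with $P$ the 29×29 symbol-pair score
table (residue–residue: substitution matrix; residue–gap type: that
type's scaled penalty; gap–gap: 0).  Terminal penalties apply to gap
runs flanking the receiving profile (a run keeps its opposite index
constant, so the decision is per run); traceback ties are broken in
fixed order MATCH > gap-in-Y > gap-in-X for determinism.  Direct
transitions between the two gap states are allowed: with gap-type
correction, consecutive gap columns in both profiles can genuinely
score higher, so the classic no-double-gap pruning is unsound here.

Gap typing truth is *positional*: per row, runs touching either end
are terminal (first gap `To`, rest `Te`), interior runs open with `Go`
and extend with `Ge`.  The S1–S6 rules maintain exactly this
classification incrementally when a column is inserted (S1/S4 also
retype the neighbouring gap); the suite property-checks incremental
against from-scratch typing on random rows.  Because the DP's
profile-level terminal heuristic can disagree with per-row typing
after correction, the reported score of a merge is the model score of
the realized merge; a package counter
(`correction_mismatches()`) tracks how often the DP objective and the
realized score differ.  This makes the reported scores exactly
self-consistent by construction, at the price of the DP being — like
the scheme it implements — a heuristic without a global optimality
guarantee.  For single gapless sequences no correction can trigger,
and the DP provably equals a textbook affine (Gotoh) aligner with
terminal gap penalties; the suite asserts exact equality on $10^3$
random pairs against an independent implementation, and exhaustive
matching enumeration on tiny profiles confirms equality in the
gapless-profile case and dominance otherwise.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `go`, `ge` | −14.85, −1.25 | matrix score units | interior gap open/extension |
| `to`, `te` | −0.66, −0.66 | matrix score units | terminal open/extension |
| `g_l`, `g_d` | 45, 7 | sequences, — | scaler threshold/divisor |
| `iterations` | 100 | proposals | refinement length |
| `k_max` | 1000 | sequences | refinement auto-gate |

The scaler is $1$ for $k \le g_l$ and $1 + \log_2(k/g_l)/g_d$ beyond —
continuous at the threshold and non-decreasing.  This closed form is a
design choice of this package, consistent with the default constants
and with the intent of stiffening gaps in large families; it is
configurable (`-gsl`, `-gsd`), as are the four penalty magnitudes
(`-go -ge -tgo -tge`), which are tunables without external authority.
MIQS is used raw (floating point, no rescaling); ambiguity codes are
filled by group means (B~{N,D}, Z~{Q,E}, U~C, O~K, X~all), rounded to
one decimal.

### Stage IV — refinement

Iterations are *proposals*, not acceptances.  A proposal splits rows
by gap presence in one uniformly chosen gapped column; the chosen
column always has at least one gap and one residue (no output column
is all-gap), so neither side of the split is empty.  Acceptance
requires a strictly greater model score — rejecting equal scores
prevents cycling.  The RNG is seeded (default 0), so default runs are
reproducible; different seeds may legitimately give different (all
non-decreasing) outcomes.

## The synthetic generator

`generate_family()` evolves a uniform random ancestor into $k$
independent descendants (star phylogeny): per-site substitution with
probability `sub_rate` (uniform over the other 19 residues), per-site
indel events with probability `indel_rate`, geometric lengths (mean 2)
capped at `max_indel`, insertion/deletion equiprobable.  Insertions of
different descendants are never homologous and get separate true-alignment
columns.  The generator emulates divergence level and indel structure,
*not* realistic evolution: no rate heterogeneity across sites, no
substitution-matrix bias, no insertion-sequence homology, star topology
by default.  Passing recovery tests therefore shows the pipeline
reassembles families whose truth is known and simple; it does not
certify accuracy on real benchmark families with deep non-star
phylogenies.

The recovery smoke threshold (SP ≥ 0.9 on families with
`sub_rate ≤ 0.05`, `indel_rate ≤ 0.01`, `k ≤ 50`) is an artifact
choice for regression protection, not an externally claimed accuracy.

## Problem sizes in the suite

Oracle-equivalence checks use $10^3$ random pairs (LCS up to length
300, Gotoh up to length 30 — the oracle is a deliberately naive R
implementation), single-linkage matrices up to $k = 100$, exhaustive
matching enumeration up to width 4 profiles, and 20 end-to-end
pipeline runs on families of 4–12 sequences; these sizes exercise
every code path (word boundaries, degenerate lengths, width-1
profiles) while keeping the default suite quick.

## Known limitations

- Alignment is computed serially; the `-t` flag is accepted for
  interface compatibility and results are by construction identical
  for any worker count.  Parallel pair batches would change timings,
  never results.
- The DP optimum is heuristic under gap correction (see above); scores
  reported are realized model scores.
- `upgma_tree()` materializes the full matrix (documented $O(k^2)$);
  `distance_matrix()` export is guarded at $k \le 5000$.
- Nucleotide input, FASTQ and compressed files are out of scope;
  position-specific matrices and matrix estimation are not provided.
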