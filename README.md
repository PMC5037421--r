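# lcsmsa

Progressive multiple sequence alignment (MSA) of protein families in R,
built for the regime where a family holds thousands of members and the
classic all-pairs + profile-merge recipe has to be engineered carefully to
stay fast and memory-frugal.

The package implements the full four-stage pipeline as a library plus a
small command-line tool:

1. **Pairwise similarities from the longest common subsequence (LCS).**
   For sequences *A* and *B* the LCS length is the maximal number of
   perfectly matching columns of any gapped pairing.  It is normalised by
   the indel distance

   `indel(A, B) = |A| + |B| − 2·LCS(A, B)`

   giving the similarity `sim = LCS/indel` and the clustering distance
   `dist = indel/LCS`.  LCS lengths are computed by a bit-parallel kernel
   (64 dynamic-programming cells per machine word) that is
   property-checked against the textbook DP recurrence.

2. **Guide tree by single linkage with the SLINK algorithm.**  SLINK
   consumes the distance matrix one row at a time and keeps only two
   pointer arrays, so stages 1–2 need `O(k)` memory for `k` sequences —
   the full `k×k` matrix is never stored.  UPGMA, chained (caterpillar)
   trees and imported Newick trees are available as alternatives, along
   with tree statistics: the Sackin index and the reference-coverage
   fraction with its Monte-Carlo baseline.

3. **Progressive profile merging.**  Aligned rows are held in a *gapped
   representation*: residue codes plus a per-residue counter of gaps
   immediately before it, indexed by a heap-ordered prefix-sum tree
   (`dps`) for `O(log n)` column↔residue mapping.  Inserting a gap column
   touches counters, never residues.  Profile–profile alignment is a
   three-state affine DP over per-column symbol counters (25 residue + 4
   gap-type slots) scored with the MIQS substitution matrix.  Gaps come in
   four types — terminal open `To`, terminal extension `Te`, gap open
   `Go`, gap extension `Ge` — and local correction rules (S1–S6) retype
   neighbouring gaps on insertion so that open counts are not
   overestimated.  All four penalties are scaled by
   `1 + log2(k/g_l)/g_d` for `k > g_l` (defaults `g_l = 45`, `g_d = 7`),
   which keeps large families from ballooning in width.  Because
   correction breaks the classic no-double-gap argument, the DP also
   explores adjacent gap columns in both profiles.

4. **Column-oriented iterative refinement.**  Repeatedly pick a random
   gapped column, split the rows by gap presence there, drop empty
   columns, realign the two subprofiles, and accept the result only if
   its sum-of-pairs model score strictly improves.  By default 100
   iterations, applied automatically for families of at most 1000
   sequences.

Alignment quality against a reference is measured by the sum-of-pairs
(SP) and total-column (TC) fractions, and a synthetic family generator
(ancestor + substitutions + geometric indels, with the implied true
alignment) provides ground truth for testing.

## Worked example

```r
library(lcsmsa)

fam <- generate_family(k = 8, root_len = 40, sub_rate = 0.1,
                       indel_rate = 0.05, max_indel = 3, seed = 42)

pair_stats(fam$sequences$sequences[[1]], fam$sequences$sequences[[2]])
#> $lcs   30    $indel 24    $sim 1.25    $dist 0.8

aln <- msa_align(fam$sequences)   # SLINK tree, MIQS, auto refinement
aln
#> <alignment> k = 8 rows, 49 columns

sp_tc(aln, fam$alignment)
#> SP = 0.933  TC = 0.811

sackin_index(attr(aln, "guide_tree"))
#> $raw 32    $normalized 4

attr(aln, "refine_trace")
#> 4482.4 4495.7 4606.7   # strictly increasing accepted model scores
```

`pair_stats` says the first two simulated descendants share an LCS of 30
columns at indel distance 24.  The pipeline aligns the 8 sequences into
49 columns; against the generator's true alignment 93.3% of residue
pairs and 81.1% of full columns are reproduced.  The refinement accepted
two proposals, raising the model score from 4482.4 to 4606.7.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/lcsmsa simulate -k 8 -len 40 -seed 42 fam.fasta truth.fasta
Rscript inst/cli/lcsmsa align -gt sl -v fam.fasta out.fasta
Rscript inst/cli/lcsmsa score --ref truth.fasta out.fasta
```

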