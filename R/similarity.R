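## Stage I: LCS-based pairwise similarity and the streamed distance rows
## consumed by guide-tree construction.

#' Longest common subsequence length (reference DP)
#'
#' Straightforward O(|A||B|) dynamic programming; serves as the oracle for
#' the bit-parallel kernel.
#'
#' @param a,b `msa_sequence` objects (or integer code vectors).
#' @return integer LCS length.
#' @export
lcs_dp <- function(a, b) {
  .lcs_dp_cpp(seq_codes(a), seq_codes(b))
}

#' Longest common subsequence length (bit-parallel)
#'
#' Packs 64 DP cells per machine word; processes `ceil(min(|A|,|B|)/64)`
#' words per row.  Returns exactly the same value as [lcs_dp()] for every
#' input.
#'
#' @inheritParams lcs_dp
#' @return integer LCS length.
#' @export
lcs_bitparallel <- function(a, b) {
  .lcs_bitparallel_cpp(seq_codes(a), seq_codes(b))
}

seq_codes <- function(x) {
  if (inherits(x, "msa_sequence")) return(x$res)
  stopifnot(is.numeric(x), length(x) >= 1L)
  as.integer(x)
}

#' Pairwise LCS statistics
#'
#' `indel = |A| + |B| - 2*lcs`; `sim = lcs/indel`; `dist = indel/lcs`.
#' Degenerate cases: identical sequences (`indel = 0`) give `dist = 0` and
#' `sim = Inf`; `lcs = 0` gives `sim = 0` and the finite distance sentinel
#' `|A| + |B| + 1`, larger than any attainable distance, so that clustering
#' always consumes finite ordered values.
#'
#' @inheritParams lcs_dp
#' @return list with fields `lcs`, `indel`, `sim`, `dist`.
#' @export
pair_stats <- function(a, b) {
  ca <- seq_codes(a); cb <- seq_codes(b)
  l <- .lcs_bitparallel_cpp(ca, cb)
  indel <- length(ca) + length(cb) - 2L * l
  sim <- if (indel > 0L) l / indel else Inf
  dist <- if (l > 0L) indel / l else length(ca) + length(cb) + 1
  list(lcs = l, indel = indel, sim = sim, dist = dist)
}

#' Streamed rows of the pairwise distance matrix
#'
#' Returns a stream object whose `row(i)` yields the distances
#' `d(i, 1..i-1)` (the strict lower triangle, one row at a time), so a
#' consumer such as [slink_tree()] never needs to hold more than one row
#' beyond its own O(k) state.  Values are deterministic functions of the
#' input pair, independent of how rows are batched.
#'
#' @param x an `msa_seqset`, or a symmetric numeric distance matrix
#'   (convenience for precomputed distances).
#' @return an object of class `msa_dist_stream` with fields `k` and
#'   `row(i)`.
#' @export
distance_rows <- function(x) UseMethod("distance_rows")

#' @export
distance_rows.msa_seqset <- function(x) {
  stopifnot(x$k >= 2L)
  seqs <- x$sequences
  structure(list(
    k = x$k,
    labels = seqset_ids(x),
    row = function(i) {
      if (i < 1L || i > length(seqs)) stop("row index out of range")
      if (i == 1L) return(numeric(0))
      vapply(seq_len(i - 1L),
             function(j) pair_stats(seqs[[i]], seqs[[j]])$dist, 0)
    }),
    class = "msa_dist_stream")
}

#' @export
distance_rows.matrix <- function(x) {
  stopifnot(nrow(x) == ncol(x), nrow(x) >= 2L)
  structure(list(
    k = nrow(x),
    labels = rownames(x),
    row = function(i) if (i == 1L) numeric(0) else as.numeric(x[i, seq_len(i - 1L)])),
    class = "msa_dist_stream")
}

#' Full pairwise distance matrix
#'
#' Materializes the stream into a symmetric k x k matrix with zero diagonal.
#' Quadratic in memory; guarded at `k <= 5000` to avoid accidental dumps.
#'
#' @param x an `msa_seqset` or a distance stream.
#' @return numeric matrix.
#' @export
distance_matrix <- function(x) {
  rows <- if (inherits(x, "msa_dist_stream")) x else distance_rows(x)
  k <- rows$k
  if (k > 5000L) stop("distance_matrix is guarded at k <= 5000", call. = FALSE)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) {
    if (i == 1L) next
    r <- rows$row(i)
    d[i, seq_len(i - 1L)] <- r
    d[seq_len(i - 1L), i] <- r
  }
  d
}
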