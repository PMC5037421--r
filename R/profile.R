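## The gapped sequence representation and the profile container used by the
## progressive stage.
##
## A gapped sequence stores an aligned row without gap characters: the
## residue codes, a `no_gaps` counter per slot giving the number of gaps
## immediately before that residue (one extra guard slot counts trailing
## gaps), and `dps`, a heap-ordered prefix-sum tree over the per-slot column
## counts (1 + no_gaps, guard: no_gaps only) enabling O(log n)
## column <-> residue coordinate mapping.  The heap follows
## dps[i] = dps[2i] + dps[2i+1]; its leaves cover two slots each and its
## root equals the realized row width.
##
## A profile bundles gapped member rows with per-column occurrence counters
## over the extended alphabet (25 residues + 4 gap types); every column's
## counter sum equals the number of members.

## ---------------------------------------------------------------------------
## dps heap helpers.  Slots are 0-based (0 .. nslots-1), columns 0-based.
## Heap is a 1-based vector of length M-1 where M = next power of two >=
## nslots (minimum 2); leaf for slot j sits at index M/2 + j %/% 2.
## ---------------------------------------------------------------------------

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- 2L * p
  max(p, 2L)
}

## slot widths in columns: 1 + no_gaps for residue slots, no_gaps for guard
slot_widths <- function(nsym, no_gaps) {
  w <- no_gaps
  w[seq_len(nsym)] <- w[seq_len(nsym)] + 1L
  w
}

build_dps <- function(nsym, no_gaps) {
  nslots <- nsym + 1L
  M <- next_pow2(nslots)
  w <- integer(M)
  w[seq_len(nslots)] <- slot_widths(nsym, no_gaps)
  dps <- integer(M - 1L)
  half <- M %/% 2L
  for (t in seq_len(half))                       # leaves cover slots 2t-2, 2t-1
    dps[half + t - 1L] <- w[2L * t - 1L] + w[2L * t]
  if (half > 1L) for (i in (half - 1L):1L)
    dps[i] <- dps[2L * i] + dps[2L * i + 1L]
  dps
}

#' Build a gapped sequence from an aligned row
#'
#' @param row aligned row: a character string over residues and `-`/`.`, or
#'   an integer code vector with 0 for gaps.
#' @param id optional id carried along.
#' @return an object of class `msa_gapped` with fields `symbols`,
#'   `no_gaps` (guard slot last), `dps`, and `width`.
#' @export
gapped_from_string <- function(row, id = NULL) {
  if (is.character(row)) {
    ch <- strsplit(toupper(row), "")[[1L]]
    codes <- integer(length(ch))
    isgap <- ch %in% c("-", ".")
    if (any(!isgap))
      codes[!isgap] <- encode_residues(paste(ch[!isgap], collapse = ""))
    row <- codes
  }
  row <- as.integer(row)
  if (!any(row != GAP_CODE)) stop("all-gap row", call. = FALSE)
  respos <- which(row != GAP_CODE)
  symbols <- row[respos]
  prev <- c(0L, respos)
  no_gaps <- c(respos - prev[-length(prev)] - 1L,
               length(row) - respos[length(respos)])
  new_gapped(symbols, no_gaps, id)
}

new_gapped <- function(symbols, no_gaps, id = NULL) {
  stopifnot(length(no_gaps) == length(symbols) + 1L)
  structure(list(symbols = as.integer(symbols),
                 no_gaps = as.integer(no_gaps),
                 dps = build_dps(length(symbols), as.integer(no_gaps)),
                 id = id),
            class = "msa_gapped")
}

#' @export
print.msa_gapped <- function(x, ...) {
  cat("<gapped sequence>", length(x$symbols), "residues, width",
      gapped_width(x), "\n")
  invisible(x)
}

#' Realized width of a gapped sequence
#'
#' Equals the dps root: residues plus all counted gaps.
#'
#' @param gs an `msa_gapped`.
#' @return integer column count.
#' @export
gapped_width <- function(gs) gs$dps[1L]

#' Expand a gapped sequence into its realized row
#'
#' @param gs an `msa_gapped`.
#' @return integer vector of width columns, 0 = gap; inverse of
#'   [gapped_from_string()].
#' @export
realize <- function(gs) {
  n <- length(gs$symbols)
  reps <- rep.int(1L, 2L * n + 1L)
  vals <- integer(2L * n + 1L)
  reps[2L * seq_len(n) - 1L] <- gs$no_gaps[seq_len(n)]
  vals[2L * seq_len(n)] <- gs$symbols
  reps[2L * n + 1L] <- gs$no_gaps[n + 1L]
  rep.int(vals, reps)
}

#' Map a column to its residue slot
#'
#' Descends the dps tree in O(log n).  Returns the 1-based slot index of
#' the residue occupying `col`, or `NA` when the column falls on a gap.
#' `position_to_column()` is the inverse for residue slots.
#'
#' @param gs an `msa_gapped`.
#' @param col 0-based column, `0 <= col < width`.
#' @return slot index or `NA_integer_`.
#' @export
column_to_position <- function(gs, col) {
  loc <- locate_column(gs, col)
  if (loc$is_gap) NA_integer_ else loc$slot
}

## Shared descent: returns the slot owning `col` (the residue slot whose
## gap-run or residue contains it; guard slot for trailing gaps) plus
## whether the column is a gap and the column of the slot's residue.
locate_column <- function(gs, col) {
  width <- gs$dps[1L]
  if (col < 0L || col >= width) stop("column ", col, " out of range [0, ",
                                     width, ")", call. = FALSE)
  n <- length(gs$symbols)
  M <- next_pow2(n + 1L)
  i <- 1L
  rem <- col
  while (i < M %/% 2L) {                     # descend to a leaf
    left <- gs$dps[2L * i]
    if (rem < left) i <- 2L * i
    else { rem <- rem - left; i <- 2L * i + 1L }
  }
  slot <- 2L * (i - M %/% 2L) + 1L           # first slot under this leaf
  repeat {
    g <- gs$no_gaps[slot]
    has_res <- slot <= n
    if (rem < g) return(list(slot = slot, is_gap = TRUE,
                             res_col = col - rem + g))
    if (has_res && rem == g) return(list(slot = slot, is_gap = FALSE,
                                         res_col = col))
    rem <- rem - g - as.integer(has_res)
    slot <- slot + 1L
  }
}

#' @rdname column_to_position
#' @param slot 1-based residue slot index.
#' @export
position_to_column <- function(gs, slot) {
  n <- length(gs$symbols)
  stopifnot(slot >= 1L, slot <= n)
  M <- next_pow2(n + 1L)
  half <- M %/% 2L
  leaf <- half + (slot - 1L) %/% 2L
  ## columns before this leaf: sum of left siblings along the root path
  before <- 0L
  i <- leaf
  while (i > 1L) {
    if (i %% 2L == 1L) before <- before + gs$dps[i - 1L]
    i <- i %/% 2L
  }
  ## within the leaf
  first <- 2L * ((slot - 1L) %/% 2L) + 1L
  if (slot > first) before <- before + gs$no_gaps[first] + 1L
  before + gs$no_gaps[slot]
}

## Add `count` gaps to slot's run and update the dps path.
bump_gaps <- function(gs, slot, count) {
  gs$no_gaps[slot] <- gs$no_gaps[slot] + as.integer(count)
  M <- next_pow2(length(gs$symbols) + 1L)
  i <- M %/% 2L + (slot - 1L) %/% 2L
  while (i >= 1L) {
    gs$dps[i] <- gs$dps[i] + as.integer(count)
    i <- i %/% 2L
  }
  gs
}

## ---------------------------------------------------------------------------
## Positional gap typing.  The four types are fully determined by run
## position: a run touching column 0 or the right end is terminal (first gap
## To, rest Te); interior runs open with Go and extend with Ge.  The local
## correction rules in gap_model.R maintain exactly this classification
## incrementally.
## ---------------------------------------------------------------------------

## Type of the gap at `col` lying in the run before `slot` (guard slot =
## n+1 for the trailing run).  `run_start` is the first column of that run.
gap_type_in_run <- function(gs, slot, col, run_start) {
  n <- length(gs$symbols)
  if (slot == 1L) {                    # leading run: starts at column 0
    if (col == 0L) TO_CODE else TE_CODE
  } else if (slot == n + 1L) {         # trailing run
    if (col == run_start) TO_CODE else TE_CODE
  } else {
    if (col == run_start) GO_CODE else GE_CODE
  }
}

#' Typed realization of a gapped sequence
#'
#' Realizes the row with every gap classified positionally as To/Te/Go/Ge
#' (codes 26..29); the reference for counter bookkeeping.
#'
#' @param gs an `msa_gapped`.
#' @return integer vector over codes 1..29.
#' @export
realize_typed <- function(gs) {
  typed_row(realize(gs))
}

## From-scratch typing of a realized row (0 = gap).
typed_row <- function(row) {
  out <- row
  n <- length(row)
  isgap <- row == GAP_CODE
  if (!any(isgap)) return(out)
  r <- rle(isgap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nruns <- length(r$lengths)
  for (q in seq_len(nruns)) {
    if (!r$values[q]) next
    s <- starts[q]; e <- ends[q]
    codes <- rep.int(if (s == 1L || e == n) TE_CODE else GE_CODE, e - s + 1L)
    codes[1L] <- if (s == 1L || e == n) TO_CODE else GO_CODE
    out[s:e] <- codes
  }
  out
}

## ---------------------------------------------------------------------------
## Profile container.
## ---------------------------------------------------------------------------

new_profile <- function(members, counters, seq_index) {
  structure(list(members = members, counters = counters,
                 width = ncol(counters), k = length(members),
                 seq_index = seq_index),
            class = "msa_profile")
}

#' @export
print.msa_profile <- function(x, ...) {
  cat("<profile> k =", x$k, "sequences, width", x$width, "\n")
  invisible(x)
}

#' Single-sequence profile
#'
#' @param seq an `msa_sequence`.
#' @param index sequence index carried for row ordering of the final
#'   alignment.
#' @return an `msa_profile` of width `|seq|`.
#' @export
profile_from_sequence <- function(seq, index = 1L) {
  gs <- new_gapped(seq$res, integer(length(seq$res) + 1L), seq$id)
  counters <- matrix(0L, N_SYM, length(seq$res),
                     dimnames = list(symbol_labels(), NULL))
  counters[cbind(seq$res, seq_len(length(seq$res)))] <- 1L
  new_profile(list(gs), counters, index)
}

#' Profile from an existing alignment
#'
#' Rows become gapped members; counters are computed from the positional
#' gap typing of each row.
#'
#' @param aln an `msa_alignment`.
#' @param seq_index optional integer row tags (default `1:k`).
#' @return an `msa_profile`.
#' @export
profile_from_alignment <- function(aln, seq_index = seq_len(nrow(aln$mat))) {
  members <- lapply(seq_len(nrow(aln$mat)), function(i)
    gapped_from_string(aln$mat[i, ], aln$ids[i]))
  counters <- count_typed_rows(
    t(matrix(vapply(seq_len(nrow(aln$mat)),
                    function(i) typed_row(aln$mat[i, ]),
                    integer(ncol(aln$mat))), nrow = ncol(aln$mat))))
  new_profile(members, counters, as.integer(seq_index))
}

## typed rows (k x width) -> counter matrix (N_SYM x width)
count_typed_rows <- function(typed) {
  apply(typed, 2L, tabulate, nbins = N_SYM)
}

#' Realize a profile as an alignment
#'
#' Rows are ordered by the profile's sequence indices.
#'
#' @param p an `msa_profile`.
#' @return an `msa_alignment`.
#' @export
profile_alignment <- function(p) {
  mat <- realize_members(p, realize)
  ids <- vapply(p$members, function(m) m$id %||% "", "")
  ord <- order(p$seq_index)
  new_alignment(mat[ord, , drop = FALSE], ids[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## k x width matrix of realized member rows (robust to width-1 profiles,
## where vapply would drop to a vector).
realize_members <- function(p, fn) {
  t(matrix(vapply(p$members, fn, integer(p$width)), nrow = p$width))
}

## Recompute counters from realized member rows; oracle for the incremental
## bookkeeping.
recount_profile <- function(p) {
  count_typed_rows(realize_members(p, realize_typed))
}

## ---------------------------------------------------------------------------
## Gap-column insertion.
## ---------------------------------------------------------------------------

#' Insert gap columns into a profile
#'
#' Inserts `count` all-gap columns before 0-based column `col` (i.e. at
#' positions `col .. col+count-1` of the widened profile).  Member rows are
#' updated by bumping gap counters and dps paths only -- no residue is
#' rewritten -- and the per-column counters are maintained incrementally,
#' including the gap-type correction of a neighbouring gap (rules S1/S4).
#'
#' @param p an `msa_profile`.
#' @param col 0-based insertion column, `0 <= col <= width`.
#' @param count number of columns (>= 1).
#' @return the widened `msa_profile`.
#' @export
insert_gap_columns <- function(p, col, count = 1L) {
  stopifnot(col >= 0L, col <= p$width, count >= 1L)
  counters <- matrix(0L, N_SYM, p$width + count,
                     dimnames = list(symbol_labels(), NULL))
  keep_before <- seq_len(col)
  if (col > 0L) counters[, keep_before] <- p$counters[, keep_before]
  if (col < p$width)
    counters[, (col + count + 1L):(p$width + count)] <-
      p$counters[, (col + 1L):p$width]
  members <- p$members
  for (mi in seq_along(members)) {
    ins <- classify_gap_insertion(members[[mi]], col, count)
    members[[mi]] <- bump_gaps(members[[mi]], ins$slot, count)
    counters[cbind(ins$types, col + seq_len(count))] <-
      counters[cbind(ins$types, col + seq_len(count))] + 1L
    if (!is.null(ins$retype)) {
      at <- ins$retype$col + count + 1L      # 1-based, after the shift
      counters[ins$retype$from, at] <- counters[ins$retype$from, at] - 1L
      counters[ins$retype$to, at] <- counters[ins$retype$to, at] + 1L
    }
  }
  new_profile(members, counters, p$seq_index)
}

## ---------------------------------------------------------------------------
## Profile merging.
## ---------------------------------------------------------------------------

#' Merge two profiles under a DP column matching
#'
#' `ops` is the monotone operation list produced by the aligner
#' (1 = MATCH, 2 = GAP_IN_X consuming a Y column, 3 = GAP_IN_Y consuming an
#' X column).  Member rows are moved, not copied; gap columns are inserted
#' run-by-run into the receiving profile.
#'
#' @param x,y `msa_profile` objects.
#' @param ops integer operation vector.
#' @return the merged `msa_profile` with `k = kx + ky`.
#' @export
merge_profiles <- function(x, y, ops) {
  if (sum(ops != 2L) != x$width || sum(ops != 3L) != y$width)
    stop("ops do not consume the profile columns exactly", call. = FALSE)
  ## insert runs left to right; out position advances over ops
  for (side in c(2L, 3L)) {
    target <- if (side == 2L) x else y
    r <- rle(ops == side)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in seq_along(r$lengths)) {
      if (!r$values[q]) next
      target <- insert_gap_columns(target, starts[q] - 1L, r$lengths[q])
    }
    if (side == 2L) x <- target else y <- target
  }
  stopifnot(x$width == length(ops), y$width == length(ops))
  new_profile(c(x$members, y$members), x$counters + y$counters,
              c(x$seq_index, y$seq_index))
}
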