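## FASTA input/output and the basic sequence containers.

new_sequence <- function(id, res, full_id = id) {
  structure(list(id = id, full_id = full_id, res = as.integer(res)),
            class = "msa_sequence")
}

#' @export
length.msa_sequence <- function(x) length(x$res)

#' @export
print.msa_sequence <- function(x, ...) {
  cat("<sequence> ", x$id, " (", length(x$res), " residues)\n", sep = "")
  invisible(x)
}

new_seqset <- function(sequences) {
  structure(list(sequences = sequences, k = length(sequences)),
            class = "msa_seqset")
}

#' @export
length.msa_seqset <- function(x) x$k

#' @export
print.msa_seqset <- function(x, ...) {
  cat("<sequence set> k =", x$k, "sequences, lengths",
      paste(range(vapply(x$sequences, function(s) length(s$res), 1L)),
            collapse = ".."), "\n")
  invisible(x)
}

#' Sequence-set accessors
#'
#' @param x an `msa_seqset`.
#' @return `seqset_ids()`: character vector of sanitized ids;
#'   `seqset_lengths()`: integer vector of sequence lengths.
#' @export
seqset_ids <- function(x) vapply(x$sequences, function(s) s$id, "")

#' @rdname seqset_ids
#' @export
seqset_lengths <- function(x) vapply(x$sequences, function(s) length(s$res), 1L)

#' Build a sequence set from named residue strings
#'
#' Convenience constructor used throughout the examples and tests.
#'
#' @param x named character vector of residue strings (gaps not allowed).
#' @return an `msa_seqset`.
#' @export
as_seqset <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  seqs <- Map(function(id, s) new_sequence(id, encode_residues(s)), ids, x)
  names(seqs) <- NULL
  check_seqset_ids(vapply(seqs, function(s) s$id, ""))
  new_seqset(seqs)
}

check_seqset_ids <- function(ids) {
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate sequence id after sanitization: '", dup, "' (record ",
         which(ids == dup)[2L], ")", call. = FALSE)
  }
  invisible(TRUE)
}

sanitize_id <- function(header) sub("\\s.*$", "", header)

#' Read sequences from a FASTA file
#'
#' Records are returned in file order.  Residues are uppercased; the gap
#' characters `-` and `.` are stripped (so aligned FASTA is accepted as
#' unaligned input); letters outside the 25-letter alphabet map to X with a
#' warning.  Ids are the headers truncated at the first whitespace (the full
#' header is retained for output).
#'
#' @param path FASTA file.
#' @return an `msa_seqset`.
#' @export
read_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(raw)
  strs <- as.character(raw)
  strs <- gsub("[-.]", "", strs)
  len0 <- which(nchar(strs) == 0L)
  if (length(len0))
    stop("zero-length record ", len0[1L], " ('", headers[len0[1L]], "') in ",
         path, call. = FALSE)
  ids <- sanitize_id(headers)
  check_seqset_ids(ids)
  seqs <- Map(function(id, h, s) new_sequence(id, encode_residues(s), h),
              ids, headers, strs)
  names(seqs) <- NULL
  new_seqset(seqs)
}

#' Write sequences or an alignment to FASTA
#'
#' Alignments are written with `-` as the gap character; rows keep their
#' stored order.  Full headers (when present) are emitted.
#'
#' @param x an `msa_seqset` or `msa_alignment`.
#' @param path output file.
#' @param width line-wrap column count (default 60).
#' @export
write_fasta <- function(x, path, width = 60L) {
  UseMethod("write_fasta")
}

.write_fasta_strings <- function(ids, strs, path, width) {
  stopifnot(width >= 1L, all(nchar(strs) >= 1L))
  set <- Biostrings::BStringSet(strs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(NULL)
}

#' @export
write_fasta.msa_seqset <- function(x, path, width = 60L) {
  ids <- vapply(x$sequences, function(s) s$full_id, "")
  strs <- vapply(x$sequences, function(s) decode_residues(s$res), "")
  .write_fasta_strings(ids, strs, path, width)
}

#' @export
write_fasta.msa_alignment <- function(x, path, width = 60L) {
  .write_fasta_strings(x$ids, alignment_strings(x), path, width)
}

## ---------------------------------------------------------------------------
## Alignment container: k x width integer matrix, 0 = gap, rows named by id.
## ---------------------------------------------------------------------------

new_alignment <- function(mat, ids) {
  stopifnot(is.matrix(mat), nrow(mat) == length(ids))
  structure(list(mat = mat, ids = ids, width = ncol(mat)),
            class = "msa_alignment")
}

#' Build an alignment object from aligned residue strings
#'
#' @param x named character vector of equal-length aligned rows
#'   (`-` or `.` for gaps).
#' @return an `msa_alignment`.
#' @export
as_alignment <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  w <- unique(nchar(x))
  if (length(w) != 1L) stop("aligned rows differ in width", call. = FALSE)
  mat <- t(matrix(vapply(x, function(row) {
    ch <- strsplit(toupper(row), "")[[1L]]
    out <- integer(length(ch))
    isgap <- ch %in% c("-", ".")
    if (any(!isgap)) out[!isgap] <- encode_residues(paste(ch[!isgap], collapse = ""))
    out
  }, integer(w)), nrow = w))
  dimnames(mat) <- NULL
  new_alignment(mat, ids)
}

#' Render alignment rows as gapped strings
#'
#' @param aln an `msa_alignment`.
#' @return character vector of rows (gap = `-`).
#' @export
alignment_strings <- function(aln) {
  apply(aln$mat, 1L, decode_residues)
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("<alignment> k =", nrow(x$mat), "rows,", x$width, "columns\n")
  invisible(x)
}

#' Read an aligned FASTA file as an alignment
#'
#' All records must have the same width; gap characters `-` and `.` are
#' accepted.
#'
#' @param path aligned FASTA file.
#' @return an `msa_alignment`.
#' @export
read_alignment <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sanitize_id(names(raw))
  check_seqset_ids(ids)
  strs <- as.character(raw)
  names(strs) <- ids
  as_alignment(strs)
}

#' Strip gaps from an alignment
#'
#' @param aln an `msa_alignment`.
#' @return an `msa_seqset` with the gap-free rows in row order.
#' @export
strip_gaps <- function(aln) {
  seqs <- lapply(seq_len(nrow(aln$mat)), function(i) {
    r <- aln$mat[i, ]
    new_sequence(aln$ids[i], r[r != GAP_CODE])
  })
  new_seqset(seqs)
}

## Validate the structural invariants of an alignment (equal widths are
## guaranteed by the matrix; checks gap-strip identity and all-gap columns).
assert_valid_alignment <- function(aln, set = NULL) {
  if (any(colSums(aln$mat != GAP_CODE) == 0L))
    stop("alignment contains an all-gap column", call. = FALSE)
  if (!is.null(set)) {
    stripped <- strip_gaps(aln)
    ord <- match(seqset_ids(set), seqset_ids(stripped))
    stopifnot(!anyNA(ord))
    same <- all(vapply(seq_along(ord), function(i) {
      identical(stripped$sequences[[ord[i]]]$res, set$sequences[[i]]$res)
    }, TRUE))
    if (!same) stop("gap-stripped alignment does not reproduce the input",
                    call. = FALSE)
  }
  invisible(TRUE)
}
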