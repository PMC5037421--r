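## Residue alphabet and integer encoding.
##
## Codes 1..20 are the standard amino acids in classic substitution-matrix
## order, 21..25 the ambiguity/rare codes B, Z, X, U, O.  Codes 26..29 are
## the four gap-type symbols used in profile counters: terminal open (TO),
## terminal extension (TE), gap open (GO), gap extension (GE).  Together the
## 29 codes fill the 32-slot per-column counter layout (3 slots spare).

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_EXT <- c(AA20, "B", "Z", "X", "U", "O")

N_RES <- 25L
TO_CODE <- 26L
TE_CODE <- 27L
GO_CODE <- 28L
GE_CODE <- 29L
N_SYM <- 29L
GAP_CODE <- 0L

GAP_TYPE_NAMES <- c("To", "Te", "Go", "Ge")

.code_of <- {
  v <- integer(256)
  v[utf8ToInt(paste(AA_EXT, collapse = ""))] <- seq_len(N_RES)
  v
}

#' Encode a residue string as integer alphabet codes
#'
#' Uppercases the input; the 20 standard amino acids and B, Z, X, U, O map
#' to distinct codes, any other letter maps to X (code of "X") with a
#' warning.  Gap characters are not accepted here (see
#' [gapped_from_string()] for aligned rows).
#'
#' @param x single character string of residues.
#' @return integer vector of codes in `1:25`.
#' @export
encode_residues <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ints <- utf8ToInt(toupper(x))
  codes <- .code_of[ints]
  if (any(codes == 0L)) {
    bad <- unique(intToUtf8(ints[codes == 0L], multiple = TRUE))
    warning("unknown residue letter(s) ", paste(bad, collapse = ", "),
            " mapped to X", call. = FALSE)
    codes[codes == 0L] <- .code_of[utf8ToInt("X")]
  }
  codes
}

#' Decode integer alphabet codes back to a residue string
#'
#' Code 0 renders as the gap character `-`.
#'
#' @param codes integer vector of codes in `0:25`.
#' @return single character string.
#' @export
decode_residues <- function(codes) {
  chars <- c("-", AA_EXT)[codes + 1L]
  paste(chars, collapse = "")
}

## Symbol labels over the extended (residue + gap-type) alphabet,
## used for counter row names and debugging output.
symbol_labels <- function() c(AA_EXT, GAP_TYPE_NAMES)
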