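## Substitution matrices: the built-in MIQS table and a loader for
## NCBI/EMBOSS-style whitespace-delimited score files.
##
## MIQS values are vendored as a constant (20 x 20, order ARNDCQEGHILKMFPSTWYV,
## floating point, no integer rescaling).  Columns for the ambiguity/rare
## codes B, Z, X, U, O are filled by averaging the corresponding standard
## residues (B ~ {N,D}, Z ~ {Q,E}, U ~ {C}, O ~ {K}, X ~ all 20), rounded to
## one decimal, which keeps the filled matrix symmetric.

.MIQS20 <- matrix(c(
  # A     R     N     D     C     Q     E     G     H     I     L     K     M     F     P     S     T     W     Y     V
   3.2, -1.3, -0.4, -0.4,  1.5, -0.2, -0.4,  0.4, -1.2, -1.3, -1.4, -0.7, -1.0, -2.3, -0.1,  0.8,  0.8, -3.6, -2.4,  0.0,
  -1.3,  6.2, -0.1, -1.5, -2.7,  1.8, -0.7, -1.9,  0.9, -2.4, -2.5,  3.3, -1.1, -3.3, -1.1, -0.3, -0.9, -3.8, -1.9, -2.3,
  -0.4, -0.1,  5.1,  2.6, -1.6,  0.9,  0.8,  0.2,  1.0, -3.6, -3.5,  0.7, -2.3, -3.5, -1.4,  0.9,  0.0, -4.5, -1.5, -2.6,
  -0.4, -1.5,  2.6,  5.7, -3.7,  0.9,  2.7, -0.5,  0.3, -4.5, -4.6,  0.4, -3.3, -5.8, -0.3,  0.3, -0.2, -5.3, -3.9, -3.5,
   1.5, -2.7, -1.6, -3.7, 11.7, -2.8, -3.2, -1.7, -1.2,  0.2, -2.3, -3.2,  0.1, -2.8, -2.8,  1.0,  0.0, -6.1, -0.7,  1.8,
  -0.2,  1.8,  0.9,  0.9, -2.8,  3.6,  2.1, -1.6,  1.2, -2.2, -1.9,  1.7, -0.4, -2.4, -0.4,  0.4,  0.1, -5.4, -2.8, -1.8,
  -0.4, -0.7,  0.8,  2.7, -3.2,  2.1,  3.6, -1.5, -0.2, -3.3, -2.8,  1.2, -2.3, -4.7,  0.0,  0.2, -0.4, -5.8, -2.6, -2.3,
   0.4, -1.9,  0.2, -0.5, -1.7, -1.6, -1.5,  7.6, -1.6, -5.4, -4.8, -1.7, -3.6, -4.6, -1.6,  0.0, -1.9, -4.8, -4.5, -3.8,
  -1.2,  0.9,  1.0,  0.3, -1.2,  1.2, -0.2, -1.6,  7.5, -2.2, -1.9,  0.0, -2.1,  0.0, -1.5,  0.0, -0.2, -0.3,  2.1, -2.3,
  -1.3, -2.4, -3.6, -4.5,  0.2, -2.2, -3.3, -5.4, -2.2,  4.6,  3.1, -2.3,  1.7,  0.7, -3.7, -2.8, -0.7, -0.7, -0.8,  3.3,
  -1.4, -2.5, -3.5, -4.6, -2.3, -1.9, -2.8, -4.8, -1.9,  3.1,  4.6, -2.4,  3.2,  2.1, -2.8, -2.9, -1.6, -0.2,  0.0,  2.0,
  -0.7,  3.3,  0.7,  0.4, -3.2,  1.7,  1.2, -1.7,  0.0, -2.3, -2.4,  3.6, -1.1, -3.7, -0.1,  0.0,  0.0, -4.0, -2.3, -2.0,
  -1.0, -1.1, -2.3, -3.3,  0.1, -0.4, -2.3, -3.6, -2.1,  1.7,  3.2, -1.1,  6.5,  2.0, -2.8, -1.8, -0.8, -2.2,  0.0,  1.3,
  -2.3, -3.3, -3.5, -5.8, -2.8, -2.4, -4.7, -4.6,  0.0,  0.7,  2.1, -3.7,  2.0,  7.0, -4.3, -2.6, -2.2,  4.4,  5.6, -0.5,
  -0.1, -1.1, -1.4, -0.3, -2.8, -0.4,  0.0, -1.6, -1.5, -3.7, -2.8, -0.1, -2.8, -4.3,  8.4, -0.1, -0.5, -5.0, -4.8, -2.5,
   0.8, -0.3,  0.9,  0.3,  1.0,  0.4,  0.2,  0.0,  0.0, -2.8, -2.9,  0.0, -1.8, -2.6, -0.1,  3.1,  1.6, -4.2, -1.8, -1.6,
   0.8, -0.9,  0.0, -0.2,  0.0,  0.1, -0.4, -1.9, -0.2, -0.7, -1.6,  0.0, -0.8, -2.2, -0.5,  1.6,  3.8, -5.2, -2.1,  0.0,
  -3.6, -3.8, -4.5, -5.3, -6.1, -5.4, -5.8, -4.8, -0.3, -0.7, -0.2, -4.0, -2.2,  4.4, -5.0, -4.2, -5.2, 14.8,  4.9, -3.3,
  -2.4, -1.9, -1.5, -3.9, -0.7, -2.8, -2.6, -4.5,  2.1, -0.8,  0.0, -2.3,  0.0,  5.6, -4.8, -1.8, -2.1,  4.9,  8.3, -1.2,
   0.0, -2.3, -2.6, -3.5,  1.8, -1.8, -2.3, -3.8, -2.3,  3.3,  2.0, -2.0,  1.3, -0.5, -2.5, -1.6,  0.0, -3.3, -1.2,  3.5),
  nrow = 20L, byrow = TRUE, dimnames = list(AA20, AA20))

## Groups whose mean fills each extra code's scores.
.AMBIG_FILL <- list(B = c("N", "D"), Z = c("Q", "E"), X = AA20,
                    U = "C", O = "K")

new_submatrix <- function(name, scores) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  structure(list(name = name, scores = scores), class = "msa_submatrix")
}

#' @export
print.msa_submatrix <- function(x, ...) {
  cat("<substitution matrix>", x$name, "-", nrow(x$scores), "x",
      ncol(x$scores), "\n")
  invisible(x)
}

.expand_to_alphabet <- function(m20, name) {
  full <- matrix(NA_real_, N_RES, N_RES, dimnames = list(AA_EXT, AA_EXT))
  present <- intersect(rownames(m20), AA_EXT)
  full[present, present] <- m20[present, present]
  missing <- setdiff(AA_EXT, present)
  for (a in missing) {
    grp <- .AMBIG_FILL[[a]]
    for (b in AA_EXT) {
      if (b %in% missing) next
      full[a, b] <- full[b, a] <- round(mean(m20[grp, b]), 1L)
    }
  }
  ## pairs of two filled codes: mean over both groups (symmetric by
  ## construction since the base matrix is)
  for (a in missing) for (b in missing) {
    full[a, b] <- round(mean(m20[.AMBIG_FILL[[a]], .AMBIG_FILL[[b]],
                                 drop = FALSE]), 1L)
  }
  stopifnot(!anyNA(full), isTRUE(all.equal(full, t(full), tolerance = 0)))
  new_submatrix(name, full)
}

.builtin_matrices <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$MIQS)) {
      stopifnot(isTRUE(all.equal(.MIQS20, t(.MIQS20), tolerance = 0)))
      cache$MIQS <- .expand_to_alphabet(.MIQS20, "MIQS")
    }
    list(MIQS = cache$MIQS)
  }
})

#' Load a substitution matrix
#'
#' `load_matrix("MIQS")` returns the built-in MIQS matrix expanded over the
#' 25-letter alphabet.  Any other argument is treated as a path to an
#' NCBI/EMBOSS-style whitespace-delimited score table (`#` comments allowed,
#' first non-comment line holds the column letters).  File matrices must be
#' exactly symmetric; residues absent from the file are filled by the
#' averaging policy used for MIQS where possible.
#'
#' @param x `"MIQS"` or a file path.
#' @return an `msa_submatrix` whose `scores` cover every alphabet pair.
#' @export
load_matrix <- function(x = "MIQS") {
  if (x %in% names(.builtin_matrices())) return(.builtin_matrices()[[x]])
  if (!file.exists(x)) stop("unknown builtin or missing file: ", x,
                            call. = FALSE)
  lines <- readLines(x)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("malformed matrix file: ", x, call. = FALSE)
  cols <- toupper(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (!all(cols %in% c(AA_EXT, "*")))
    stop("unknown residue label in matrix header: ",
         paste(setdiff(cols, AA_EXT), collapse = ","), call. = FALSE)
  n <- length(cols)
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  labs <- toupper(vapply(rows, `[`, "", 1L))
  if (!all(labs %in% c(AA_EXT, "*")))
    stop("unknown residue label in matrix rows: ",
         paste(setdiff(labs, AA_EXT), collapse = ","), call. = FALSE)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(n)))
  dimnames(vals) <- list(labs, cols)
  keep <- setdiff(intersect(labs, cols), "*")
  vals <- vals[keep, keep, drop = FALSE]
  if (!identical(vals, t(vals))) {
    bad <- which(vals != t(vals), arr.ind = TRUE)[1L, ]
    stop("asymmetric matrix file: score(", keep[bad[1L]], ",",
         keep[bad[2L]], ") != score(", keep[bad[2L]], ",", keep[bad[1L]],
         ")", call. = FALSE)
  }
  if (max(vals[cbind(keep, keep)]) < max(vals))
    warning("matrix has an off-diagonal entry above the best diagonal score",
            call. = FALSE)
  if (all(AA20 %in% keep)) {
    .expand_to_alphabet(vals, basename(x))
  } else {
    new_submatrix(basename(x), vals)
  }
}
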