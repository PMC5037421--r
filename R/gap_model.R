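## Four-type affine gap model: terminal/internal gap open and extension
## penalties, the set-size scaling factor, and the local gap-type
## correction rules applied when gap columns are inserted into a profile.

#' Affine gap model
#'
#' Penalties are negative score-unit values (magnitudes may be given; they
#' are forced negative).  All four penalties are multiplied by the set-size
#' scaling factor [gap_scaler()] computed from `k`: families larger than
#' `g_l` get proportionally stiffer gaps, which prevents unnecessary
#' widening of alignments of large collections.  The default magnitudes
#' (Go 14.85, Ge 1.25, To 0.66, Te 0.66) are tunables of this package, not
#' values with any external authority.
#'
#' @param go,ge,to,te gap open / extension, terminal open / extension
#'   penalties.
#' @param g_l scaling threshold constant (default 45).
#' @param g_d scaling divisor constant (default 7).
#' @param k number of sequences in the input collection (drives the
#'   scaler; default 1 gives scaler 1).
#' @return an object of class `msa_gap_model` with scaled penalties in
#'   fields `go`, `ge`, `to`, `te` and the `scaler` used.
#' @export
gap_model <- function(go = -14.85, ge = -1.25, to = -0.66, te = -0.66,
                      g_l = 45, g_d = 7, k = 1L) {
  pen <- -abs(c(go = go, ge = ge, to = to, te = te))
  if (abs(pen["ge"]) > abs(pen["go"]) || abs(pen["te"]) > abs(pen["to"]))
    warning("extension penalty exceeds open penalty", call. = FALSE)
  s <- gap_scaler(k, g_l, g_d)
  structure(list(go = unname(pen["go"]) * s, ge = unname(pen["ge"]) * s,
                 to = unname(pen["to"]) * s, te = unname(pen["te"]) * s,
                 g_l = g_l, g_d = g_d, k = as.integer(k), scaler = s),
            class = "msa_gap_model")
}

#' @export
print.msa_gap_model <- function(x, ...) {
  cat(sprintf("<gap model> Go=%.3f Ge=%.3f To=%.3f Te=%.3f (scaler %.4f, k=%d)\n",
              x$go, x$ge, x$to, x$te, x$scaler, x$k))
  invisible(x)
}

#' Set-size gap-penalty scaling factor
#'
#' `1` for `k <= g_l`, otherwise `1 + log2(k / g_l) / g_d`: continuous at
#' the threshold and non-decreasing in `k`.  The closed form is a
#' configurable choice of this package consistent with the default
#' constants `g_l = 45`, `g_d = 7`.
#'
#' @param k number of sequences (>= 1).
#' @param g_l threshold constant (default 45).
#' @param g_d divisor constant (default 7).
#' @return scaler >= 1.
#' @export
gap_scaler <- function(k, g_l = 45, g_d = 7) {
  stopifnot(k >= 1, g_l >= 1, g_d > 0)
  ifelse(k <= g_l, 1, 1 + log2(k / g_l) / g_d)
}

#' Penalty of a gap-type symbol
#'
#' @param type gap-type code (26..29) or name (`"To"`, `"Te"`, `"Go"`,
#'   `"Ge"`).
#' @param model an `msa_gap_model`.
#' @return the scaled penalty.
#' @export
gap_score <- function(type, model) {
  if (is.character(type)) type <- TO_CODE - 1L + match(type, GAP_TYPE_NAMES)
  switch(type - N_RES, model$to, model$te, model$go, model$ge,
         stop("unknown gap type code: ", type, call. = FALSE))
}

#' Pairwise column-symbol score over the extended alphabet
#'
#' Residue-residue pairs score by the substitution matrix; a residue
#' against a gap-type symbol scores that type's scaled penalty; two gap
#' symbols score 0.
#'
#' @param a,b symbol codes in 1..29 (or residue letters / gap-type names).
#' @param matrix an `msa_submatrix`.
#' @param model an `msa_gap_model`.
#' @return numeric score.
#' @export
pair_gap_score <- function(a, b, matrix, model) {
  code <- function(x) {
    if (is.character(x)) {
      g <- match(x, GAP_TYPE_NAMES)
      if (!is.na(g)) return(N_RES + g)
      return(match(x, AA_EXT))
    }
    as.integer(x)
  }
  pair_score_matrix(matrix, model)[code(a), code(b)]
}

## Full 29 x 29 score table used by the DP and the model score.
pair_score_matrix <- function(matrix, model) {
  P <- matrix(0, N_SYM, N_SYM,
              dimnames = list(symbol_labels(), symbol_labels()))
  P[seq_len(N_RES), seq_len(N_RES)] <- matrix$scores[AA_EXT, AA_EXT]
  pens <- c(model$to, model$te, model$go, model$ge)
  for (g in seq_along(pens)) {
    P[seq_len(N_RES), N_RES + g] <- pens[g]
    P[N_RES + g, seq_len(N_RES)] <- pens[g]
  }
  P
}

## ---------------------------------------------------------------------------
## Gap-type correction rules.
##
## When a gap column is inserted into a profile, each member row receives a
## gap whose type depends on its local context; in two situations the
## neighbouring gap must be retyped so that open/extension counts are not
## overestimated:
##   S1 terminal open at the right  -> insert To, neighbour To -> Te
##   S2 terminal extension at left  -> insert Te
##   S3 inside a gap series         -> insert Ge
##   S4 gap open at the right       -> insert Go, neighbour Go -> Ge
##   S5 lone gap between residues   -> insert Go
##   S6 terminal open at the left   -> insert Te
## Insertion at a row terminus next to residues opens a terminal series
## (To), the terminal analogue of S5.  The rules reproduce the from-scratch
## positional typing of the whole row (property-tested).
## ---------------------------------------------------------------------------

#' Classify a single inserted gap
#'
#' Determines the gap type a row assigns to a gap inserted before 0-based
#' column `col`, plus an optional retype instruction for the neighbouring
#' gap (rules S1/S4), without modifying the row.
#'
#' @param gs an `msa_gapped` row.
#' @param col insertion column, `0 <= col <= width`.
#' @return list with `type` (code), `type_name`, and `retype` (`NULL` or
#'   `list(col, from, to)` in pre-insertion column coordinates).
#' @export
classify_inserted_gap <- function(gs, col) {
  ins <- classify_gap_insertion(gs, col, 1L)
  list(type = ins$types[1L],
       type_name = GAP_TYPE_NAMES[ins$types[1L] - N_RES],
       retype = ins$retype)
}

## Vectorized variant for a run of `count` gaps inserted at `col`:
## the first gap follows the single-gap rules, the remainder extend it.
classify_gap_insertion <- function(gs, col, count) {
  n <- length(gs$symbols)
  width <- gs$dps[1L]
  stopifnot(col >= 0L, col <= width)
  retype <- NULL
  if (col == width) {
    slot <- n + 1L
    if (gs$no_gaps[slot] > 0L) {
      first <- TE_CODE                         # S2/S6: trailing run at left
    } else {
      first <- TO_CODE                         # opens a right-terminal series
    }
  } else {
    loc <- locate_column(gs, col)
    slot <- loc$slot
    g <- gs$no_gaps[slot]
    run_start <- loc$res_col - g               # first column of the run
    if (loc$is_gap && col == run_start) {
      ## left neighbour residue/BOS, right neighbour = old first gap of run
      right <- gap_type_in_run(gs, slot, col, run_start)
      if (right == TO_CODE) {                  # S1
        first <- TO_CODE
        retype <- list(col = run_start, from = TO_CODE, to = TE_CODE)
      } else {                                 # S4 (right == Go)
        first <- GO_CODE
        retype <- list(col = run_start, from = GO_CODE, to = GE_CODE)
      }
    } else if (loc$is_gap) {
      ## inside the run: left neighbour is a gap of the same run
      left <- gap_type_in_run(gs, slot, col - 1L, run_start)
      first <- if (left %in% c(TO_CODE, TE_CODE)) TE_CODE else GE_CODE
    } else if (g > 0L) {
      ## before a residue, at the end of its preceding run
      left <- gap_type_in_run(gs, slot, col - 1L, col - g)
      first <- if (left %in% c(TO_CODE, TE_CODE)) TE_CODE else GE_CODE
    } else if (col == 0L) {
      first <- TO_CODE                         # opens the row at the left end
    } else {
      first <- GO_CODE                         # S5: lone gap between residues
    }
  }
  rest <- if (first %in% c(TO_CODE, TE_CODE)) TE_CODE else GE_CODE
  list(slot = slot, types = c(first, rep.int(rest, count - 1L)),
       retype = retype)
}
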