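## Synthetic protein-family generator.
##
## A random ancestral sequence over the 20 standard residues evolves into k
## independent descendants (star phylogeny): per-site substitutions at rate
## `sub_rate`, and per-site indel events at rate `indel_rate` whose lengths
## are geometric, capped at `max_indel`.  Insertions of different
## descendants are never homologous, so the implied true alignment places
## them in separate columns; that alignment is returned alongside the
## sequences and serves as an SP/TC reference.

#' Generate a synthetic protein family with its true alignment
#'
#' @param k number of descendants (>= 2).
#' @param root_len ancestral sequence length (>= 1).
#' @param sub_rate per-site substitution probability in `[0, 1]`.
#' @param indel_rate per-site indel event probability in `[0, 1]`.
#' @param max_indel indel length cap (>= 1).
#' @param seed RNG seed; runs are deterministic per seed.
#' @return list with `sequences` (an `msa_seqset`, ids `t1..tk`) and
#'   `alignment` (the true `msa_alignment`).
#' @export
generate_family <- function(k, root_len = 100L, sub_rate = 0.1,
                            indel_rate = 0.02, max_indel = 5L, seed = 0L) {
  stopifnot(k >= 2L, root_len >= 1L, sub_rate >= 0, sub_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, max_indel >= 1L)
  with_seed(seed, {
    root <- sample.int(20L, root_len, replace = TRUE)
    keep <- matrix(TRUE, k, root_len)        # root site survives in descendant
    resid <- matrix(root, k, root_len, byrow = TRUE)
    ins <- vector("list", k)                 # insertions keyed by gap slot 0..root_len
    for (d in seq_len(k)) {
      ins[[d]] <- vector("list", root_len + 1L)
      ## indel events, left to right over root sites
      site <- 1L
      while (site <= root_len) {
        if (stats::runif(1) < indel_rate) {
          len <- min(stats::rgeom(1L, 0.5) + 1L, max_indel)
          if (stats::runif(1) < 0.5) {
            ## deletion of sites site..site+len-1 (clipped)
            del <- site:min(site + len - 1L, root_len)
            ## never delete the descendant's last surviving site
            if (sum(keep[d, ]) - length(del) >= 1L) keep[d, del] <- FALSE
            site <- site + length(del)
            next
          } else {
            ins[[d]][[site]] <- sample.int(20L, len, replace = TRUE)
          }
        }
        site <- site + 1L
      }
      ## substitutions on surviving sites
      hit <- which(keep[d, ] & stats::runif(root_len) < sub_rate)
      if (length(hit))
        resid[d, hit] <- 1L + (resid[d, hit] - 1L +
                               sample.int(19L, length(hit), replace = TRUE)) %% 20L
    }
    ## build the true alignment: per gap slot g (before root site g+1, plus
    ## the terminal slot root_len+1), each descendant's insertion gets its
    ## own block of columns, ordered by descendant index
    blocks <- list()
    for (g in seq_len(root_len + 1L)) {
      for (d in seq_len(k)) {
        iv <- ins[[d]][[g]]
        if (g <= root_len && !is.null(iv)) {
          col <- matrix(GAP_CODE, k, length(iv))
          col[d, ] <- iv
          blocks[[length(blocks) + 1L]] <- col
        }
      }
      if (g <= root_len) {
        col <- matrix(GAP_CODE, k, 1L)
        col[keep[, g], 1L] <- resid[keep[, g], g]
        if (any(keep[, g])) blocks[[length(blocks) + 1L]] <- col
      }
    }
    mat <- do.call(cbind, blocks)
    ids <- paste0("t", seq_len(k))
    aln <- new_alignment(mat, ids)
    list(sequences = strip_gaps(aln), alignment = aln)
  })
}
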