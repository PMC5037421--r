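## Stage II: guide-tree construction (SLINK single linkage, UPGMA, chained),
## Newick import/export, and tree statistics.
##
## A guide tree is stored hclust-style: `merge` is a (k-1) x 2 integer
## matrix whose negative entries reference leaves (sequence indices 1..k)
## and positive entries earlier merge rows; `height` holds the merge
## heights; `labels` the leaf ids in sequence-index order.  Row order is a
## valid post-order for the progressive stage (children before parents).

new_guide_tree <- function(merge, height, labels, method) {
  k <- length(labels)
  stopifnot(nrow(merge) == k - 1L, length(height) == k - 1L)
  structure(list(merge = merge, height = height, labels = labels,
                 k = k, method = method),
            class = "msa_guide_tree")
}

#' @export
print.msa_guide_tree <- function(x, ...) {
  cat("<guide tree>", x$method, "- k =", x$k, "leaves\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## SLINK (Sibson's pointer-representation single linkage).
## ---------------------------------------------------------------------------

#' Single-linkage guide tree via SLINK
#'
#' Consumes the distance rows one at a time, keeping only the two
#' pointer-representation arrays (pi, lambda) and the current row, i.e. O(k)
#' auxiliary memory; the full matrix is never materialized.  The pointer
#' representation is converted to a binary dendrogram by processing points
#' in ascending (lambda, index) order, so exact ties merge the smaller
#' sequence index first.
#'
#' @param rows an `msa_dist_stream` (see [distance_rows()]) or an
#'   `msa_seqset`/matrix accepted by it.
#' @param labels optional leaf labels (defaults to stream labels or
#'   `"s1".."sk"`).
#' @return an `msa_guide_tree`.
#' @export
slink_tree <- function(rows, labels = NULL) {
  rows <- as_dist_stream(rows)
  k <- rows$k
  pi <- integer(k); lambda <- numeric(k)
  pi[1L] <- 1L; lambda[1L] <- Inf
  for (i in seq_len(k)[-1L]) {
    pi[i] <- i; lambda[i] <- Inf
    m <- rows$row(i)
    if (length(m) != i - 1L) stop("distance row ", i, " has length ",
                                  length(m), ", expected ", i - 1L,
                                  call. = FALSE)
    for (j in seq_len(i - 1L)) {
      if (lambda[j] >= m[j]) {
        m[pi[j]] <- min(m[pi[j]], lambda[j])
        lambda[j] <- m[j]
        pi[j] <- i
      } else {
        m[pi[j]] <- min(m[pi[j]], m[j])
      }
    }
    for (j in seq_len(i - 1L)) {
      if (lambda[j] >= lambda[pi[j]]) pi[j] <- i
    }
  }
  pointer_to_tree(pi, lambda, guess_labels(labels, rows, k), "single")
}

## Convert (pi, lambda) to a merge matrix: union-find over points processed
## in ascending (lambda, index) order.
pointer_to_tree <- function(pi, lambda, labels, method) {
  k <- length(pi)
  ord <- order(lambda[-k], seq_len(k - 1L))
  parent <- seq_len(2L * k - 1L)            # union-find over nodes
  node_of <- -seq_len(k)                    # cluster representative -> node ref
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  merge <- matrix(0L, k - 1L, 2L)
  height <- numeric(k - 1L)
  for (r in seq_len(k - 1L)) {
    j <- ord[r]
    a <- find(j); b <- find(pi[j])
    merge[r, ] <- c(node_of[a], node_of[b])
    height[r] <- lambda[j]
    parent[a] <- b
    node_of[b] <- r
  }
  new_guide_tree(merge, height, labels, method)
}

as_dist_stream <- function(x) {
  if (inherits(x, "msa_dist_stream")) x else distance_rows(x)
}

guess_labels <- function(labels, rows, k) {
  if (!is.null(labels)) return(labels)
  if (!is.null(rows$labels)) return(rows$labels)
  paste0("s", seq_len(k))
}

## ---------------------------------------------------------------------------
## UPGMA (average linkage), naive O(k^3): adequate at guide-tree test scale
## and cross-checked against stats::hclust in the suite.  Documented O(k^2)
## memory: the full matrix is held.
## ---------------------------------------------------------------------------

#' Average-linkage (UPGMA) guide tree
#'
#' @inheritParams slink_tree
#' @return an `msa_guide_tree`.
#' @export
upgma_tree <- function(rows, labels = NULL) {
  rows <- as_dist_stream(rows)
  k <- rows$k
  labels <- guess_labels(labels, rows, k)
  d <- distance_matrix(rows)
  diag(d) <- Inf
  active <- rep(TRUE, k)
  size <- rep(1L, k)
  node <- -seq_len(k)
  merge <- matrix(0L, k - 1L, 2L)
  height <- numeric(k - 1L)
  for (r in seq_len(k - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    pos <- arrayInd(which.min(t(sub)), dim(sub))[, 2:1]  # row-major: smallest i, then j
    i <- idx[min(pos)]; j <- idx[max(pos)]
    merge[r, ] <- c(node[i], node[j])
    height[r] <- d[i, j]
    ## weighted average update into slot i
    w <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    d[i, ] <- w; d[, i] <- w; d[i, i] <- Inf
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    node[i] <- r
  }
  new_guide_tree(merge, height, labels, "upgma")
}

## ---------------------------------------------------------------------------
## Chained (caterpillar) tree.
## ---------------------------------------------------------------------------

#' Chained (caterpillar) guide tree
#'
#' Maximally imbalanced topology `((..((s1,s2),s3)..),sk)` over the given
#' leaf order; merge heights are the merge ranks.  Requires no distances.
#'
#' @param k number of leaves.
#' @param order permutation of `1:k` giving the chaining order, or `NULL` to
#'   draw one uniformly using `seed`.
#' @param seed RNG seed used when `order` is `NULL` (default 0).
#' @param labels optional leaf labels.
#' @return an `msa_guide_tree`.
#' @export
chained_tree <- function(k, order = NULL, seed = 0L, labels = NULL) {
  stopifnot(k >= 2L)
  if (is.null(order)) {
    order <- with_seed(seed, sample.int(k))
  }
  if (!identical(sort(as.integer(order)), seq_len(k)))
    stop("order is not a permutation of 1..k", call. = FALSE)
  order <- as.integer(order)
  merge <- matrix(0L, k - 1L, 2L)
  merge[1L, ] <- c(-order[1L], -order[2L])
  if (k > 2L) for (r in 2L:(k - 1L)) merge[r, ] <- c(r - 1L, -order[r + 1L])
  if (is.null(labels)) labels <- paste0("s", seq_len(k))
  new_guide_tree(merge, seq_len(k - 1L), labels, "chained")
}

## Evaluate expr with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---------------------------------------------------------------------------
## Newick import/export (parsing via ape; export by direct string building,
## no branch lengths -- only the topology drives the progressive stage).
## ---------------------------------------------------------------------------

#' Import a guide tree from a Newick file
#'
#' The tree must be rooted and strictly binary; branch lengths are ignored.
#' When `ids` is supplied the leaf labels must be a bijection onto it, and
#' leaf indices are mapped onto positions in `ids`.
#'
#' @param path Newick file.
#' @param ids optional character vector of sequence ids to bind leaves to.
#' @return an `msa_guide_tree`.
#' @export
parse_newick <- function(path, ids = NULL) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file: ", path, call. = FALSE)
  phylo_to_tree(phy, ids)
}

phylo_to_tree <- function(phy, ids = NULL) {
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("tree has fewer than 2 leaves", call. = FALSE)
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("guide tree must be rooted and strictly binary", call. = FALSE)
  labs <- phy$tip.label
  if (!is.null(ids)) {
    if (anyDuplicated(labs)) stop("duplicate leaf label in Newick tree",
                                  call. = FALSE)
    miss <- setdiff(labs, ids)
    if (length(miss)) stop("Newick leaf label not in sequence set: '",
                           miss[1L], "'", call. = FALSE)
    miss2 <- setdiff(ids, labs)
    if (length(miss2)) stop("sequence id missing from Newick tree: '",
                            miss2[1L], "'", call. = FALSE)
    leaf_index <- match(labs, ids)
    labels <- ids
  } else {
    leaf_index <- seq_len(ntip)
    labels <- labs
  }
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  root <- ntip + 1L
  merge <- matrix(0L, ntip - 1L, 2L)
  height <- numeric(ntip - 1L)
  row_of <- integer(ntip + phy$Nnode)
  nextrow <- 0L
  visit <- function(node) {
    if (node <= ntip) return(-leaf_index[node])
    ch <- kids[[as.character(node)]]
    l <- visit(ch[1L]); r <- visit(ch[2L])
    nextrow <<- nextrow + 1L
    merge[nextrow, ] <<- c(l, r)
    height[nextrow] <<- max(0, ifelse(l > 0L, height[l], 0),
                            ifelse(r > 0L, height[r], 0)) + 1
    nextrow
  }
  visit(root)
  new_guide_tree(merge, height, labels, "imported")
}

#' Export a guide tree to Newick
#'
#' Topology only (no branch lengths).
#'
#' @param tree an `msa_guide_tree`.
#' @param path output file; `NULL` returns the Newick string.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  fmt <- function(ref) {
    if (ref < 0L) tree$labels[-ref]
    else paste0("(", fmt(tree$merge[ref, 1L]), ",",
                fmt(tree$merge[ref, 2L]), ")")
  }
  s <- paste0(fmt(nrow(tree$merge)), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

## ---------------------------------------------------------------------------
## Tree statistics.
## ---------------------------------------------------------------------------

## Depth of every leaf (root depth 0), leaf-index order.
leaf_depths <- function(tree) {
  k <- tree$k
  depth_node <- numeric(k - 1L)   # depth of each internal node
  depths <- numeric(k)
  for (r in rev(seq_len(k - 1L))) {      # parents before children top-down
    d <- if (r == nrow(tree$merge)) 0 else depth_node[r]
    for (ref in tree$merge[r, ]) {
      if (ref < 0L) depths[-ref] <- d + 1 else depth_node[ref] <- d + 1
    }
  }
  depths
}

#' Sackin index of a guide tree
#'
#' Sum of the depths of all leaves (root depth 0); the normalized variant
#' divides by the number of leaves.
#'
#' @param tree an `msa_guide_tree`.
#' @return list with `raw` and `normalized`.
#' @export
sackin_index <- function(tree) {
  raw <- sum(leaf_depths(tree))
  list(raw = raw, normalized = raw / tree$k)
}

## Number of leaves below each internal node, and per-node counts of a
## marked leaf subset.
clade_stats <- function(tree, marked) {
  k <- tree$k
  sizes <- integer(k - 1L); hits <- integer(k - 1L)
  for (r in seq_len(k - 1L)) {
    for (ref in tree$merge[r, ]) {
      if (ref < 0L) {
        sizes[r] <- sizes[r] + 1L
        hits[r] <- hits[r] + as.integer(marked[-ref])
      } else {
        sizes[r] <- sizes[r] + sizes[ref]
        hits[r] <- hits[r] + hits[ref]
      }
    }
  }
  list(sizes = sizes, hits = hits)
}

#' Guide-tree coverage of a reference subset
#'
#' The number of leaves in the smallest clade containing all of `ref_ids`,
#' divided by the total leaf count.
#'
#' @param tree an `msa_guide_tree`.
#' @param ref_ids character ids (or integer leaf indices) of the reference
#'   leaves; nonempty subset of the leaves.
#' @return fraction in (0, 1].
#' @export
covering_fraction <- function(tree, ref_ids) {
  k <- tree$k
  marked <- rep(FALSE, k)
  if (is.character(ref_ids)) {
    idx <- match(ref_ids, tree$labels)
    if (anyNA(idx)) stop("unknown leaf id: '",
                         ref_ids[which(is.na(idx))[1L]], "'", call. = FALSE)
  } else idx <- as.integer(ref_ids)
  if (length(idx) == 0L) stop("empty reference subset", call. = FALSE)
  stopifnot(all(idx >= 1L & idx <= k))
  marked[idx] <- TRUE
  m <- sum(marked)
  if (m == 1L) return(1 / k)
  cs <- clade_stats(tree, marked)
  covering <- which(cs$hits == m)
  min(cs$sizes[covering]) / k
}

#' Monte-Carlo baseline for the covering fraction
#'
#' Averages [covering_fraction()] over `trials` uniformly drawn leaf
#' subsets of size `m`.
#'
#' @param tree an `msa_guide_tree`.
#' @param m subset cardinality (2..k).
#' @param trials number of random subsets (default 1000).
#' @param seed RNG seed (default 0).
#' @return mean fraction.
#' @export
mc_covering_fraction <- function(tree, m, trials = 1000L, seed = 0L) {
  k <- tree$k
  stopifnot(m >= 1L, m <= k)
  with_seed(seed, mean(vapply(seq_len(trials), function(t)
    covering_fraction(tree, sample.int(k, m)), 0)))
}
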