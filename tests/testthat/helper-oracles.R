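# Independent oracles used across the suite.  Each is a deliberately
# naive implementation kept free of the package's internal code paths.

# Exhaustive LCS: enumerate all subsequences of the shorter sequence and
# test containment in the other.  Only for tiny inputs.
oracle_lcs_enum <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  n <- length(a)
  stopifnot(n <= 12)
  is_subseq <- function(s, t) {
    j <- 1L
    for (x in t) if (j <= length(s) && s[j] == x) j <- j + 1L
    j > length(s)
  }
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) > best && is_subseq(a[idx], b)) best <- length(idx)
  }
  best
}

# Textbook Gotoh with four-type terminal gap penalties: three score
# matrices, no traceback, plain R.
oracle_gotoh <- function(a, b, S, go, ge, to, te) {
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in a, consuming b
  Y <- matrix(NEG, n + 1, m + 1)   # gap in b, consuming a
  M[1, 1] <- 0
  X[1, 2] <- to
  if (m > 1) for (j in 3:(m + 1)) X[1, j] <- X[1, j - 1] + te
  Y[2, 1] <- to
  if (n > 1) for (i in 3:(n + 1)) Y[i, 1] <- Y[i - 1, 1] + te
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      S[a[i - 1], b[j - 1]]
    oy <- if (j - 1 == m) to else go; ey <- if (j - 1 == m) te else ge
    Y[i, j] <- max(M[i - 1, j] + oy, X[i - 1, j] + oy, Y[i - 1, j] + ey)
    ox <- if (i - 1 == n) to else go; ex <- if (i - 1 == n) te else ge
    X[i, j] <- max(M[i, j - 1] + ox, Y[i, j - 1] + ox, X[i, j - 1] + ex)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force single linkage: repeatedly merge the closest cluster pair
# under the min-distance rule; returns the sorted merge heights.
oracle_single_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        v <- min(d[clusters[[i]], clusters[[j]]])
        if (v < best) { best <- v; bi <- i; bj <- j }
      }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# All monotone column matchings of n1 x n2 columns as op vectors
# (1 = MATCH, 2 = gap in X consuming Y, 3 = gap in Y consuming X),
# optionally excluding adjacent 2/3 pairs (double-gap columns).
oracle_enum_matchings <- function(n1, n2, allow_double_gap = FALSE) {
  out <- list()
  rec <- function(i, j, ops) {
    if (i == n1 && j == n2) { out[[length(out) + 1L]] <<- ops; return() }
    last <- if (length(ops)) ops[length(ops)] else 0L
    if (i < n1 && j < n2) rec(i + 1L, j + 1L, c(ops, 1L))
    if (i < n1 && (allow_double_gap || last != 2L)) rec(i + 1L, j, c(ops, 3L))
    if (j < n2 && (allow_double_gap || last != 3L)) rec(i, j + 1L, c(ops, 2L))
  }
  rec(0L, 0L, integer(0))
  out
}

# Merge two alignment matrices under an op vector (gap code 0).
oracle_merge_mats <- function(mx, my, ops) {
  cx <- cy <- 0L
  cols <- matrix(0L, nrow(mx) + nrow(my), length(ops))
  for (p in seq_along(ops)) {
    op <- ops[p]
    if (op == 1L) {
      cx <- cx + 1L; cy <- cy + 1L
      cols[, p] <- c(mx[, cx], my[, cy])
    } else if (op == 3L) {
      cx <- cx + 1L
      cols[, p] <- c(mx[, cx], integer(nrow(my)))
    } else {
      cy <- cy + 1L
      cols[, p] <- c(integer(nrow(mx)), my[, cy])
    }
  }
  cols
}

# Random gapless sequence set.
random_seqset <- function(k, len_range = c(5L, 40L)) {
  strs <- vapply(seq_len(k), function(i) {
    n <- sample(len_range[1]:len_range[2], 1L)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
          collapse = "")
  }, "")
  names(strs) <- paste0("s", seq_len(k))
  as_seqset(strs)
}

# Random symmetric distance matrix with zero diagonal.
random_dist <- function(k) {
  d <- matrix(stats::runif(k * k), k)
  d <- d + t(d); diag(d) <- 0
  d
}

# Random aligned rows (k x w) with no all-gap column and no all-gap row.
random_alignment <- function(k, w, gap_prob = 0.3) {
  repeat {
    mat <- matrix(ifelse(stats::runif(k * w) < gap_prob, 0L,
                         sample.int(20L, k * w, TRUE)), k, w)
    if (all(rowSums(mat != 0L) > 0L)) {
      mat <- mat[, colSums(mat != 0L) > 0L, drop = FALSE]
      if (ncol(mat) >= 1L) return(new_alignment_for_test(mat))
    }
  }
}

new_alignment_for_test <- function(mat) {
  aln <- as_alignment(setNames(apply(mat, 1L, function(r)
    decode_residues(r)), paste0("s", seq_len(nrow(mat)))))
  aln
}

# Toy match/mismatch matrix over the full alphabet.
toy_matrix <- function(match = 1, mismatch = -1) {
  labs <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "U", "O")
  m <- matrix(mismatch, 25, 25, dimnames = list(labs, labs))
  diag(m) <- match
  structure(list(name = "toy", scores = m), class = "msa_submatrix")
}
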