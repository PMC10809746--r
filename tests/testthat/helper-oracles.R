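# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: string handling via strsplit,
# clustering via stats::hclust, pair counting via full enumeration.

rand_junctions <- function(n, L) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                           collapse = ""),
         character(1))
}

naive_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

naive_distance_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) m[i, j] <- m[j, i] <- naive_hamming(seqs[i], seqs[j])
    }
  }
  m
}

# Single linkage at an inclusive normalized cutoff via hclust + cutree; the
# cut height sits between the integer distances floor(cutoff*L) and
# floor(cutoff*L)+1 so inclusion at the boundary is unambiguous.
naive_single_linkage <- function(seqs, cutoff) {
  n <- length(seqs)
  if (n == 1L) return(1L)
  L <- nchar(seqs[1])
  d <- naive_distance_matrix(seqs)
  h <- stats::hclust(stats::as.dist(d), method = "single")
  stats::cutree(h, h = floor(cutoff * L + 1e-9) + 0.5)
}

# Vectorized variant of the distance oracle for larger instances: character
# matrix comparison per row, no shared code with the package kernels.
oracle_distance_matrix <- function(seqs) {
  chars <- t(vapply(strsplit(seqs, ""), identity,
                    character(nchar(seqs[1]))))
  n <- length(seqs)
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    m[, i] <- as.integer(rowSums(chars != matrix(chars[i, ], n,
                                                 ncol(chars), byrow = TRUE)))
  }
  m
}

oracle_single_linkage <- function(seqs, cutoff) {
  n <- length(seqs)
  if (n == 1L) return(1L)
  L <- nchar(seqs[1])
  d <- oracle_distance_matrix(seqs)
  h <- stats::hclust(stats::as.dist(d), method = "single")
  stats::cutree(h, h = floor(cutoff * L + 1e-9) + 0.5)
}

# Greedy lexicode reference: plain R loop over strings.
naive_lexicode <- function(points, d_min) {
  acc <- character(0)
  for (p in points) {
    if (all(vapply(acc, function(a) naive_hamming(a, p) >= d_min, logical(1)))) {
      acc <- c(acc, p)
    }
  }
  acc
}

# Pair confusion by enumeration of all unordered pairs.
naive_pair_confusion <- function(truth, predicted) {
  n <- length(truth)
  tp <- fp <- fn <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_t <- truth[i] == truth[j]
      same_p <- predicted[i] == predicted[j]
      if (same_t && same_p) tp <- tp + 1L
      if (!same_t && same_p) fp <- fp + 1L
      if (same_t && !same_p) fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Two partitions of the same elements are equal up to label renaming.
same_partition <- function(a, b) {
  identical(
    as.integer(factor(a, levels = unique(a))),
    as.integer(factor(b, levels = unique(b)))
  )
}

# Small clonal instance: k clones of given size around random germlines, with
# exactly `muts` substitutions per member so within/between distances are
# controlled precisely.
toy_clones <- function(k, size, L, muts) {
  germs <- rand_junctions(k, L)
  bases <- c("A", "C", "G", "T")
  seqs <- character(0)
  clone <- character(0)
  for (c in seq_len(k)) {
    g <- strsplit(germs[c], "")[[1]]
    for (s in seq_len(size)) {
      x <- g
      if (muts > 0) {
        pos <- sample(L, muts)
        for (p in pos) x[p] <- sample(setdiff(bases, x[p]), 1)
      }
      seqs <- c(seqs, paste(x, collapse = ""))
      clone <- c(clone, paste0("c", c))
    }
  }
  tibble::tibble(
    sequence_id = paste0("t", seq_along(seqs)),
    junction = seqs,
    true_clone_id = clone
  )
}
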