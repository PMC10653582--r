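# Independent brute-force oracles, kept deliberately naive so they share
# no code path with the package implementations they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# pairwise-loop sequence weights: pi_s = 1 / #{t : DH(s,t) < theta}
oracle_weights <- function(mat, theta) {
  n <- nrow(mat)
  w <- numeric(n)
  for (s in seq_len(n)) {
    neighbours <- 0L
    for (t in seq_len(n)) {
      dh <- sum(mat[s, ] != mat[t, ]) / ncol(mat)
      if (dh < theta) neighbours <- neighbours + 1L
    }
    w[s] <- 1 / neighbours
  }
  w
}

oracle_neff <- function(mat, theta) sum(oracle_weights(mat, theta))

# rank-then-Pearson Spearman with average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# naive UPGMA: repeatedly merge the closest pair of clusters, averaging
# distances weighted by cluster sizes; returns the sorted merge heights
oracle_upgma_heights <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  dmat <- D
  heights <- numeric(0)
  idx <- seq_len(n)
  while (length(idx) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      if (dmat[idx[a], idx[b]] < best_d) {
        best_d <- dmat[idx[a], idx[b]]
        best <- c(a, b)
      }
    }
    i <- idx[best[1L]]; j <- idx[best[2L]]
    heights <- c(heights, best_d)
    # merged cluster distances: size-weighted average
    new_d <- (sizes[i] * dmat[i, ] + sizes[j] * dmat[j, ]) /
      (sizes[i] + sizes[j])
    dmat[i, ] <- new_d
    dmat[, i] <- new_d
    sizes[i] <- sizes[i] + sizes[j]
    idx <- idx[idx != j]
  }
  sort(heights)
}

# random gapped alignment with a gap-free query row
random_alignment <- function(n, L, gap_prob = 0.1) {
  mat <- matrix(sample(AA20, n * L, replace = TRUE), n, L)
  if (n > 1L) {
    gaps <- matrix(stats::runif((n - 1L) * L) < gap_prob, n - 1L, L)
    mat[-1L, ][gaps] <- "-"
  }
  new_alignment(mat)
}

# alignment from a character vector of equal-length strings (row 1 = query)
aln_from_strings <- function(..., taxon = "unknown") {
  rows <- strsplit(c(...), "", fixed = TRUE)
  new_alignment(do.call(rbind, rows), taxon = taxon, validate = FALSE)
}

# two-clade fixture: columns can be clade-homogeneous (different residue
# per clade) or shuffled across clades with the same overall composition
clade_fixture <- function(n_per_clade = 8L, seed = 42L,
                          include_free = TRUE) {
  set.seed(seed)
  n <- 2L * n_per_clade + 1L
  # clade markers keep the two clades far apart and the query an outgroup
  # (every row mismatches the query at every marker column)
  marker <- matrix("W", n, 8L)
  marker[1L + seq_len(n_per_clade), ] <- "I"
  marker[1L + n_per_clade + seq_len(n_per_clade), ] <- "L"
  # column 9: clade-homogeneous (G in clade 1, H in clade 2, query A)
  homog <- c("A", rep("G", n_per_clade), rep("H", n_per_clade))
  # column 10: same composition shuffled across clades
  shuffled <- c("A", sample(c(rep("G", n_per_clade), rep("H", n_per_clade))))
  # column 11: fully conserved; column 12 (optional): free
  conserved <- rep("A", n)
  cols <- cbind(marker, homog, shuffled, conserved)
  if (include_free)
    cols <- cbind(cols, free = c("A", sample(AA20, n - 1L, replace = TRUE)))
  new_alignment(unname(cols))
}
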