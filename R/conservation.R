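#' Build a sequence tree from global similarities
#'
#' Agglomerative clustering (average linkage by default, i.e. UPGMA) of
#' the alignment's sequences on their pairwise normalized Hamming
#' distances. The tree summarizes how the family's sequences segregate,
#' and is the backbone against which per-position conservation is
#' measured: sites whose variation follows deep splits of this tree are
#' conserved within clades even when variable overall.
#'
#' @param aln an [Alignment] (N >= 2; a single-sequence alignment yields
#'   a degenerate one-leaf tree).
#' @param linkage linkage criterion passed to [stats::hclust()]
#'   (`"average"`, `"single"`, `"complete"`, ...). Average linkage is the
#'   default because it resists chaining on alignments dominated by
#'   near-duplicates.
#' @return an object of class `SequenceTree`: the fitted
#'   [stats::hclust] tree, its merge heights, and the leaf-to-sequence
#'   map.
#' @export
build_tree <- function(aln, linkage = "average") {
  n <- n_sequences(aln)
  if (n == 1L) {
    return(structure(list(hclust = NULL, n = 1L, heights = numeric(0),
                          leaf_ids = aln$sequence_ids, linkage = linkage),
                     class = "SequenceTree"))
  }
  # canonical leaf order (lexicographic by sequence string, ties by id)
  # makes the tree — and everything derived from it — invariant to the
  # row order of the input alignment even when pair distances tie
  strings <- apply(aln$matrix, 1L, paste, collapse = "")
  ord <- order(strings, aln$sequence_ids, seq_len(n))
  D <- hamming_matrix(aln$matrix[ord, , drop = FALSE])
  ids <- aln$sequence_ids[ord]
  dimnames(D) <- list(ids, ids)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  structure(list(hclust = hc, n = n, heights = hc$height,
                 leaf_ids = ids, leaf_rows = ord, linkage = linkage),
            class = "SequenceTree")
}

#' @export
print.SequenceTree <- function(x, ...) {
  cat(sprintf("SequenceTree: %d leaves, %s linkage, root height %.4f\n",
              x$n, x$linkage,
              if (x$n > 1L) max(x$heights) else 0))
  invisible(x)
}

#' Export a sequence tree as Newick
#'
#' @param tree a `SequenceTree` from [build_tree()].
#' @param path optional file path; when given the Newick string is also
#'   written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
tree_newick <- function(tree, path = NULL) {
  if (tree$n == 1L) {
    nwk <- paste0("(", tree$leaf_ids[[1L]], ");")
  } else {
    phy <- ape::as.phylo(tree$hclust)
    nwk <- ape::write.tree(phy)
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

# Minimum subtree size used when testing homogeneity: small clades carry
# too little evidence of ancient segregation to count.
min_subtree_size <- function(n) max(2L, as.integer(ceiling(0.05 * n)))

# Core conservation scan over all columns of `mat` given an hclust tree.
#
# Walks the merge list from the root downwards. Undoing the top merges
# one at a time enumerates the partitions of the sequences into subtrees,
# each partition labelled by the height of the merge just above it. For
# every column, the conservation level is h*/h_root where h* is the
# greatest partition height at which at least two subtrees of size >=
# m_min are homogeneous at that column (all non-gap symbols identical,
# with at least one non-gap symbol). Columns for which no partition
# qualifies get 0; columns identical across all rows get 1.
cons_levels <- function(mat, hc, m_min) {
  n <- nrow(mat)
  L <- ncol(mat)
  heights <- hc$height
  h_root <- heights[n - 1L]

  fully_conserved <- apply(mat, 2L, function(col) all(col == col[[1L]])) &
    mat[1L, ] != GAP

  if (h_root <= 0) {
    # all sequences identical: every column is fully conserved
    return(rep(1, L))
  }

  # Per-node column state: the shared symbol if the subtree is
  # homogeneous (gaps ignored), "" if the subtree is all-gap, NA if
  # heterogeneous. Leaves are rows of `mat`; merge nodes combine children.
  leaf_sym <- mat
  leaf_sym[leaf_sym == GAP] <- ""
  merge_sym <- matrix(NA_character_, n - 1L, L)
  merge_size <- integer(n - 1L)

  node_sym <- function(id) if (id < 0L) leaf_sym[-id, ] else merge_sym[id, ]
  node_size <- function(id) if (id < 0L) 1L else merge_size[id]

  combine_sym <- function(a, b) {
    out <- ifelse(a == "", b, ifelse(b == "", a,
                  ifelse(a == b, a, NA_character_)))
    out[is.na(a) | is.na(b)] <- NA_character_
    out
  }

  for (j in seq_len(n - 1L)) {
    c1 <- hc$merge[j, 1L]
    c2 <- hc$merge[j, 2L]
    merge_sym[j, ] <- combine_sym(node_sym(c1), node_sym(c2))
    merge_size[j] <- node_size(c1) + node_size(c2)
  }

  qualifies <- function(id) {
    if (node_size(id) < m_min) return(rep(FALSE, L))
    s <- node_sym(id)
    !is.na(s) & s != ""
  }

  levels <- rep(NA_real_, L)
  Q <- rep(0L, L)
  for (j in (n - 1L):1L) {
    c1 <- hc$merge[j, 1L]
    c2 <- hc$merge[j, 2L]
    if (j < n - 1L) Q <- Q - qualifies(j)    # node j splits into c1, c2
    Q <- Q + qualifies(c1) + qualifies(c2)
    hit <- is.na(levels) & Q >= 2L
    if (any(hit)) levels[hit] <- heights[j] / h_root
  }

  levels[is.na(levels)] <- 0
  levels[fully_conserved] <- 1
  pmin(pmax(levels, 0), 1)
}

#' Conservation level of one query position
#'
#' @param aln an [Alignment].
#' @param tree the `SequenceTree` built on `aln` (see [build_tree()]).
#' @param i 1-based query position.
#' @param comp_weight weight of the subordinate composition term
#'   (see [conservation_profile()]).
#' @return a real in `[0, 1]`.
#' @seealso [conservation_profile()] for all positions at once.
#' @export
position_conservation <- function(aln, tree, i, comp_weight = 0.5) {
  L <- alignment_length(aln)
  if (!(is.numeric(i) && length(i) == 1L && i >= 1L && i <= L))
    stop("position ", i, " outside 1..", L, call. = FALSE)
  profile_levels(aln, tree, comp_weight)[[as.integer(i)]]
}

# weighted fraction of the modal non-gap residue per column
modal_fraction <- function(mat) {
  apply(mat, 2L, function(col) {
    res <- col[col != GAP]
    if (length(res) == 0L) return(0)
    max(table(res)) / length(res)
  })
}

profile_levels <- function(aln, tree, comp_weight = 0.5) {
  L <- alignment_length(aln)
  if (tree$n == 1L) return(rep(1, L))
  mat <- aln$matrix[tree$leaf_rows, , drop = FALSE]  # tree leaf order
  scan <- cons_levels(mat, tree$hclust, min_subtree_size(tree$n))
  # the subtree scan is coarse: positions whose variation never forms
  # two large homogeneous subtrees all collapse to 0. A subordinate
  # composition term grades those positions by how dominated their
  # column is, without ever overriding a strong tree signal.
  levels <- scan + (1 - scan) * comp_weight * modal_fraction(aln$matrix)
  # columns supported only by the query carry no evidence
  if (nrow(aln$matrix) > 1L) {
    no_evidence <- colSums(aln$matrix[-1L, , drop = FALSE] != GAP) == 0L
    levels[no_evidence] <- 0
  }
  pmin(pmax(levels, 0), 1)
}

#' Per-position conservation profile
#'
#' Computes the conservation level of every query position against one
#' shared sequence tree. The primary signal is segregation along the
#' tree: a position is conserved when, high up in the tree, at least two
#' sizable subtrees are each homogeneous for it (all their non-gap
#' symbols identical), and the tree term is the height of the deepest
#' such partition as a fraction of the root height. Because that scan is
#' coarse — positions that never segregate into homogeneous subtrees
#' all score 0 on it — a subordinate composition term, `comp_weight`
#' times the weighted modal-residue fraction of the column, fills the
#' remaining scale: `level = s + (1 - s) * comp_weight * modal`. Fully
#' conserved columns score exactly 1; columns with no residues outside
#' the query score 0.
#'
#' @param aln a preprocessed [Alignment].
#' @param tree optional `SequenceTree`; built from `aln` when omitted.
#' @param linkage linkage used if the tree is built here.
#' @param comp_weight weight in `[0, 1]` of the composition term,
#'   default 0.5: even a fully monomorphic column can only reach half
#'   the scale on composition alone, so tree evidence always dominates.
#' @return an object of class `ConservationProfile`: `levels` (numeric,
#'   length L, in `[0, 1]`), the `tree`, and the parameters used.
#' @export
conservation_profile <- function(aln, tree = NULL, linkage = "average",
                                 comp_weight = 0.5) {
  if (is.null(tree)) tree <- build_tree(aln, linkage = linkage)
  levels <- profile_levels(aln, tree, comp_weight)
  structure(
    list(levels = levels,
         tree = tree,
         params = list(m_min = min_subtree_size(tree$n),
                       linkage = tree$linkage,
                       comp_weight = comp_weight,
                       homogeneity = "all non-gap symbols identical")),
    class = "ConservationProfile")
}

#' @export
print.ConservationProfile <- function(x, ...) {
  cat(sprintf(
    "ConservationProfile: %d positions, mean level %.3f (min %.3f, max %.3f)\n",
    length(x$levels), mean(x$levels), min(x$levels), max(x$levels)))
  invisible(x)
}
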