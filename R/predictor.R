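# Default reduced amino-acid alphabet: 11 physicochemical classes.
# Small/polar {A,S,T}; aliphatic {I,L,V}; methionine; aromatic {F,W,Y};
# basic {K,R}; acidic {D,E}; amide {N,Q}; glycine; proline; cysteine;
# histidine. Any named list covering the 20 letters exactly once can be
# supplied instead.
DEFAULT_REDUCED_ALPHABET <- list(
  AST = c("A", "S", "T"),
  ILV = c("I", "L", "V"),
  M   = "M",
  FWY = c("F", "W", "Y"),
  KR  = c("K", "R"),
  DE  = c("D", "E"),
  NQ  = c("N", "Q"),
  G   = "G",
  P   = "P",
  C   = "C",
  H   = "H")

# letter -> class-name lookup, validating the partition
reduced_class_map <- function(alphabet = DEFAULT_REDUCED_ALPHABET) {
  letters_seen <- unlist(alphabet, use.names = FALSE)
  if (!setequal(letters_seen, AA_LETTERS) ||
      length(letters_seen) != length(AA_LETTERS))
    stop("reduced alphabet must partition the 20 amino acids", call. = FALSE)
  map <- rep(names(alphabet), lengths(alphabet))
  names(map) <- letters_seen
  map
}

#' Weighted amino-acid frequencies per column
#'
#' Computes, for every query position, the weighted frequency of each
#' reduced-alphabet class and of each of the 20 amino acids. Counts are
#' weighted by the per-sequence weights (so redundant sequences do not
#' dominate), a pseudocount `lambda` is added per class, and columns are
#' normalized with gaps excluded from the denominator.
#'
#' @param aln an [Alignment].
#' @param weights per-sequence weights from [sequence_weights()];
#'   uniform by default.
#' @param lambda pseudocount added to every class before normalization,
#'   default 1.
#' @param alphabet reduced alphabet, a named list partitioning the 20
#'   amino acids into classes.
#' @return a list with matrices `reduced` (L x K) and `full` (L x 20),
#'   each row summing to 1, plus the `class_map` letter-to-class lookup.
#'   All-gap columns get the uniform distribution with a warning.
#' @export
reduced_frequencies <- function(aln, weights = NULL, lambda = 1,
                                alphabet = DEFAULT_REDUCED_ALPHABET) {
  mat <- aln$matrix
  n <- nrow(mat)
  L <- ncol(mat)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0), lambda >= 0)
  map <- reduced_class_map(alphabet)
  classes <- names(alphabet)
  K <- length(classes)

  red <- matrix(0, L, K, dimnames = list(NULL, classes))
  full <- matrix(0, L, length(AA_LETTERS),
                 dimnames = list(NULL, AA_LETTERS))
  all_gap <- logical(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    keep <- col != GAP
    if (!any(keep)) {
      all_gap[j] <- TRUE
      red[j, ] <- 1 / K
      full[j, ] <- 1 / length(AA_LETTERS)
      next
    }
    w <- weights[keep]
    aa <- col[keep]
    full_counts <- vapply(AA_LETTERS, function(a) sum(w[aa == a]),
                          numeric(1))
    red_counts <- vapply(classes,
                         function(k) sum(full_counts[alphabet[[k]]]),
                         numeric(1))
    red[j, ] <- (red_counts + lambda) / sum(red_counts + lambda)
    fc <- full_counts + lambda
    full[j, ] <- fc / sum(fc)
  }
  if (any(all_gap))
    warning(sum(all_gap), " all-gap column(s) assigned uniform frequencies")
  list(reduced = red, full = full, class_map = map)
}

# Conservation-weighted Hamming distance of every row to the query:
# sum_j c_j * [x_j != q_j] / sum_j c_j, gaps counted as mismatches.
# A flat zero profile falls back to uniform weights.
row_distances <- function(aln, cons_levels) {
  q <- aln$matrix[1L, ]
  w <- cons_levels
  if (sum(w) <= 0) w <- rep(1, length(w))
  mism <- t(aln$matrix) != q              # L x N
  as.numeric(crossprod(mism, w) / sum(w))
}

#' Evolutionary distance of a substitution
#'
#' The distance of substitution to `b` at position `i` is the minimal
#' conservation-weighted Hamming distance between the query and any
#' aligned sequence that displays `b` at `i` — the minimum amount of
#' change observed to accommodate that residue. The wild-type residue
#' always has distance 0 (the query is its own witness).
#'
#' @param aln an [Alignment].
#' @param cons a `ConservationProfile` for `aln`.
#' @param i 1-based query position.
#' @param b target amino acid (one-letter code).
#' @return a non-negative real, or `NA` when no sequence displays `b` at
#'   `i` (the substitution is unobserved).
#' @export
evolutionary_distance <- function(aln, cons, i, b) {
  L <- alignment_length(aln)
  if (!(i >= 1L && i <= L)) stop("position out of range", call. = FALSE)
  if (!(b %in% AA_LETTERS)) stop("not a canonical amino acid: ", b,
                                 call. = FALSE)
  d <- row_distances(aln, cons$levels)
  witnesses <- aln$matrix[, i] == b
  if (!any(witnesses)) return(NA_real_)
  min(d[witnesses])
}

#' Full single-site mutational landscape
#'
#' Scores every possible substitution at every query position. For each
#' position i and residue b, the raw cost is the evolutionary distance
#' δ(i, b) when b is observed in column i; when it is not, the cost falls
#' back to the cheapest observed member of b's reduced-alphabet class
#' plus a penalty `kappa`, or to the global worst observed distance plus
#' `kappa` when no such member is observed. The wild-type residue never
#' counts as class evidence: it witnesses itself trivially and says
#' nothing about tolerance to substitution. Raw costs are weighted by the
#' position's conservation level (so equal costs hurt more at conserved
#' sites), negated, and rescaled so that the landscape minimum is exactly
#' -1 and wild-type cells are exactly 0. More negative = more deleterious.
#'
#' @param aln a preprocessed [Alignment].
#' @param cons a `ConservationProfile`; computed from `aln` when omitted.
#' @param freqs frequency tables from [reduced_frequencies()]; computed
#'   when omitted (used by the optional frequency blend).
#' @param weights per-sequence weights for the frequency computation.
#' @param kappa penalty added to fallback costs, as a fraction of the
#'   worst observed distance; default 0.2.
#' @param lambda pseudocount for [reduced_frequencies()].
#' @param alpha frequency blend weight in `[0, 1]`: 0 (default) scores by
#'   distances alone; larger values mix in `1 - f_class(i, class(b))`,
#'   the rarity of b's reduced class in column i.
#' @param alphabet reduced alphabet (see [reduced_frequencies()]).
#' @return an object of class `Landscape`: `scores` (L x 20, <= 0, rows
#'   named `"<pos><wt>"`), `positions`, `wildtype`, `alphabet`, and the
#'   parameters used.
#' @export
single_landscape <- function(aln, cons = NULL, freqs = NULL,
                             weights = NULL, kappa = 0.2, lambda = 1,
                             alpha = 0,
                             alphabet = DEFAULT_REDUCED_ALPHABET) {
  L <- alignment_length(aln)
  if (L == 0L) stop("empty alignment", call. = FALSE)
  stopifnot(alpha >= 0, alpha <= 1, kappa >= 0)
  if (is.null(cons)) cons <- conservation_profile(aln)
  if (is.null(freqs))
    freqs <- reduced_frequencies(aln, weights = weights, lambda = lambda,
                                 alphabet = alphabet)
  map <- freqs$class_map
  q <- query_sequence(aln)
  d <- row_distances(aln, cons$levels)

  # observed minimal distance per (position, residue)
  delta <- matrix(NA_real_, L, length(AA_LETTERS),
                  dimnames = list(NULL, AA_LETTERS))
  for (j in seq_len(L)) {
    col <- aln$matrix[, j]
    obs <- split(d, col)
    obs <- obs[names(obs) %in% AA_LETTERS]
    if (length(obs) > 0L)
      delta[j, names(obs)] <- vapply(obs, min, numeric(1))
  }
  # the query witnesses its own residue at every position
  delta[cbind(seq_len(L), match(q, AA_LETTERS))] <- 0

  observed_max <- suppressWarnings(max(delta, na.rm = TRUE))
  # degenerate alignments (query-only) observe no change at all; the
  # worst conceivable normalized Hamming distance is 1
  delta_max <- if (!is.finite(observed_max) || observed_max <= 0) 1 else
    observed_max
  pen <- kappa * delta_max

  raw <- delta
  for (j in seq_len(L)) {
    missing_b <- AA_LETTERS[is.na(delta[j, ])]
    if (length(missing_b) == 0L) next
    for (b in missing_b) {
      # the wild type trivially witnesses itself and says nothing about
      # tolerance to substitutions, so it is not class evidence
      members <- setdiff(names(map)[map == map[[b]]], c(b, q[[j]]))
      cand <- delta[j, members]
      cand <- cand[!is.na(cand)]
      raw[j, b] <- if (length(cand) > 0L) min(cand) + pen else
        delta_max + pen
    }
  }

  if (alpha > 0) {
    rarity <- 1 - freqs$reduced[, map[colnames(raw)], drop = FALSE]
    raw <- (1 - alpha) * raw + alpha * delta_max * rarity
    raw[cbind(seq_len(L), match(q, AA_LETTERS))] <- 0
  }

  scores <- -cons$levels * raw
  low <- min(scores)
  if (low < 0) scores <- scores / abs(low)    # landscape minimum -> -1
  scores[cbind(seq_len(L), match(q, AA_LETTERS))] <- 0
  rownames(scores) <- paste0(seq_len(L), q)

  structure(
    list(scores = scores,
         positions = seq_len(L),
         wildtype = q,
         alphabet = AA_LETTERS,
         params = list(kappa = kappa, lambda = lambda, alpha = alpha,
                       delta_max = delta_max,
                       reduced_alphabet = alphabet)),
    class = "Landscape")
}

#' @export
print.Landscape <- function(x, ...) {
  cat(sprintf("Landscape: %d positions x %d residues (min %.3f)\n",
              nrow(x$scores), ncol(x$scores), min(x$scores)))
  invisible(x)
}

#' Parse a mutant string against a query sequence
#'
#' Accepts single substitutions (`"A25G"`) and colon-separated multiples
#' (`"A25G:F33L"`). Positions are 1-based in the query numbering after
#' applying `offset` (DMS position = query position + offset).
#'
#' @param s mutant string.
#' @param query query sequence (character vector or single string).
#' @param offset integer added to query positions to obtain the numbering
#'   used in `s`; default 0.
#' @return a data.frame with columns `position` (query numbering), `wt`,
#'   `mut`, of class `SubstitutionQuery`.
#' @export
parse_mutant <- function(s, query, offset = 0L) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("mutant string must be a nonempty string", call. = FALSE)
  if (length(query) == 1L && nchar(query) > 1L)
    query <- strsplit(query, "", fixed = TRUE)[[1L]]
  tokens <- strsplit(s, ":", fixed = TRUE)[[1L]]
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z])$", tokens))
  bad <- tokens[vapply(m, length, integer(1)) == 0L]
  if (length(bad) > 0L)
    stop("malformed mutant token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  wt <- vapply(m, `[[`, character(1), 2L)
  pos <- as.integer(vapply(m, `[[`, character(1), 3L)) - as.integer(offset)
  mut <- vapply(m, `[[`, character(1), 4L)
  out_of_range <- pos < 1L | pos > length(query)
  if (any(out_of_range))
    stop("position(s) out of range: ",
         paste(tokens[out_of_range], collapse = ", "), call. = FALSE)
  mismatch <- wt != query[pos]
  if (any(mismatch))
    stop("wild-type mismatch at position(s) ",
         paste0(pos[mismatch], " (query has ", query[pos[mismatch]],
                ", mutant says ", wt[mismatch], ")", collapse = "; "),
         call. = FALSE)
  if (anyDuplicated(pos))
    stop("duplicate position(s) in combined variant: ",
         paste(pos[duplicated(pos)], collapse = ", "), call. = FALSE)
  structure(data.frame(position = pos, wt = wt, mut = mut,
                       stringsAsFactors = FALSE),
            class = c("SubstitutionQuery", "data.frame"))
}

#' Score a (possibly multiple) substitution on a landscape
#'
#' Combined variants score additively: the sum of the single-substitution
#' landscape cells. A synonymous substitution scores 0.
#'
#' @param landscape a `Landscape` from [single_landscape()].
#' @param q a `SubstitutionQuery` from [parse_mutant()], or a mutant
#'   string parsed against the landscape's query.
#' @param offset numbering offset used when `q` is a string.
#' @return the combined score (a real `<= 0`).
#' @export
combined_score <- function(landscape, q, offset = 0L) {
  if (is.character(q))
    q <- parse_mutant(q, landscape$wildtype, offset = offset)
  wt_here <- landscape$wildtype[q$position]
  if (any(q$wt != wt_here))
    stop("wild-type mismatch at position(s) ",
         paste(q$position[q$wt != wt_here], collapse = ", "),
         call. = FALSE)
  sum(landscape$scores[cbind(q$position, match(q$mut, landscape$alphabet))])
}

#' Write a landscape to disk
#'
#' @param landscape a `Landscape`.
#' @param wide optional path for a wide TSV (rows = positions with the
#'   wild-type residue, columns = the 20 amino acids).
#' @param long optional path for a long CSV with columns `mutant,score`
#'   (one row per non-synonymous substitution).
#' @return invisibly, the landscape.
#' @export
write_landscape <- function(landscape, wide = NULL, long = NULL) {
  if (!is.null(wide)) {
    df <- data.frame(pos = landscape$positions,
                     wt = landscape$wildtype,
                     landscape$scores,
                     check.names = FALSE)
    utils::write.table(df, wide, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(long)) {
    grid <- expand.grid(pos = landscape$positions,
                        mut = landscape$alphabet,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid$wt <- landscape$wildtype[grid$pos]
    grid <- grid[grid$wt != grid$mut, ]
    grid <- grid[order(grid$pos, grid$mut), ]
    df <- data.frame(
      mutant = paste0(grid$wt, grid$pos, grid$mut),
      score = landscape$scores[cbind(grid$pos,
                                     match(grid$mut, landscape$alphabet))])
    utils::write.csv(df, long, row.names = FALSE, quote = FALSE)
  }
  invisible(landscape)
}
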