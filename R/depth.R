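#' Normalized Hamming distance between two aligned rows
#'
#' Fraction of positions at which two equally long aligned sequences
#' differ. A gap aligned to a residue counts as a mismatch; a gap aligned
#' to a gap counts as a match, so the self-distance of any row is 0.
#'
#' @param a,b character vectors of equal length over amino acids + `-`.
#' @return a real in `[0, 1]`.
#' @export
hamming_norm <- function(a, b) {
  if (length(a) != length(b))
    stop("rows have different lengths (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  if (length(a) == 0L) stop("rows must have length >= 1", call. = FALSE)
  mean(a != b)
}

# All pairwise normalized Hamming distances of an alignment, N x N.
# Chunked over rows so memory stays bounded for very large N; the result
# is exact and independent of the chunk size.
hamming_matrix <- function(mat, chunk_size = 512L) {
  n <- nrow(mat)
  tmat <- t(mat)                       # L x N, column-major per sequence
  D <- matrix(0, n, n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    for (s in idx) D[s, ] <- colMeans(tmat != tmat[, s])
  }
  D
}

#' Per-sequence weights from neighborhood counts
#'
#' The weight of sequence s is the reciprocal of the number of sequences
#' (including s itself) whose normalized Hamming distance to s is
#' strictly below the divergence threshold `theta_id`. Redundant
#' sequences share their unit of evidence; unique sequences keep weight 1.
#'
#' @param aln an [Alignment].
#' @param theta_id neighborhood divergence threshold in (0, 1);
#'   see [default_theta()] for the taxon defaults.
#' @return numeric vector of weights in `(0, 1]`, one per sequence.
#' @export
sequence_weights <- function(aln, theta_id = default_theta(aln$taxon)) {
  stopifnot(theta_id > 0, theta_id < 1)
  mat <- aln$matrix
  if (nrow(mat) == 0L || ncol(mat) == 0L)
    stop("empty alignment", call. = FALSE)
  D <- hamming_matrix(mat)
  1 / rowSums(D < theta_id)
}

#' Effective number of sequences (Neff)
#'
#' Sum of the per-sequence weights: N identical rows give Neff = 1,
#' N mutually divergent rows give Neff = N.
#'
#' @inheritParams sequence_weights
#' @return a real in `[1, N]`.
#' @export
neff <- function(aln, theta_id = default_theta(aln$taxon)) {
  sum(sequence_weights(aln, theta_id))
}

#' Default divergence threshold by taxon
#'
#' 0.2 (80% sequence identity) for eukaryotic, prokaryotic, human and
#' unknown proteins; 0.01 (99% identity) for viral proteins, whose
#' families are typically dominated by very similar sequences.
#'
#' @param taxon one of `"human"`, `"eukaryote"`, `"prokaryote"`,
#'   `"virus"`, `"unknown"`.
#' @return the threshold theta_id.
#' @export
default_theta <- function(taxon) {
  taxon <- match.arg(taxon, TAXA)
  if (taxon == "virus") 0.01 else 0.2
}

#' Number of well-covered alignment positions (Lcov)
#'
#' Counts query positions whose column gap fraction (over all rows) is
#' strictly below `max_gap_frac`.
#'
#' @param aln an [Alignment].
#' @param max_gap_frac gap-fraction cutoff, default 0.30.
#' @return integer `<=` L.
#' @export
coverage_length <- function(aln, max_gap_frac = 0.30) {
  stopifnot(max_gap_frac > 0, max_gap_frac <= 1)
  gap_frac <- colMeans(aln$matrix == GAP)
  sum(gap_frac < max_gap_frac)
}

#' Alignment depth report
#'
#' Bundles the depth diagnostics of an alignment: per-sequence weights,
#' Neff, L, Lcov, both Neff ratios, the threshold used and the depth
#' class.
#'
#' @inheritParams sequence_weights
#' @param max_gap_frac gap-fraction cutoff for Lcov, default 0.30.
#' @param ratio which ratio drives the classification, `"lcov"`
#'   (Neff/Lcov, default) or `"l"` (Neff/L).
#' @return an object of class `DepthReport`.
#' @export
depth_report <- function(aln, theta_id = default_theta(aln$taxon),
                         max_gap_frac = 0.30, ratio = c("lcov", "l")) {
  ratio <- match.arg(ratio)
  w <- sequence_weights(aln, theta_id)
  L <- alignment_length(aln)
  Lcov <- coverage_length(aln, max_gap_frac)
  rep <- structure(
    list(weights = w,
         neff = sum(w),
         L = L,
         Lcov = Lcov,
         ratio_L = sum(w) / L,
         ratio_Lcov = if (Lcov > 0L) sum(w) / Lcov else Inf,
         theta_id = theta_id,
         classify_by = ratio),
    class = "DepthReport")
  rep$depth_class <- classify_depth(rep, ratio = ratio)
  rep
}

#' Depth class of an alignment
#'
#' Alignments with a Neff ratio strictly below 1 are shallow (`"low"`),
#' those strictly above 100 are deep (`"high"`); everything in between —
#' including the boundary values 1 and 100, for which the defining
#' inequalities are strict — is `"medium"`.
#'
#' @param report a `DepthReport` from [depth_report()].
#' @param ratio `"lcov"` (use Neff/Lcov, default) or `"l"` (use Neff/L).
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
classify_depth <- function(report, ratio = c("lcov", "l")) {
  ratio <- match.arg(ratio)
  r <- if (ratio == "lcov") report$ratio_Lcov else report$ratio_L
  if (r < 1) "low" else if (r > 100) "high" else "medium"
}

#' @export
print.DepthReport <- function(x, ...) {
  cat(sprintf(
    "DepthReport: Neff = %.2f over N = %d sequences (theta_id = %g)\n",
    x$neff, length(x$weights), x$theta_id))
  cat(sprintf("  L = %d, Lcov = %d, Neff/L = %.3f, Neff/Lcov = %.3f\n",
              x$L, x$Lcov, x$ratio_L, x$ratio_Lcov))
  cat(sprintf("  depth class: %s (by Neff/%s)\n", x$depth_class,
              if (x$classify_by == "lcov") "Lcov" else "L"))
  invisible(x)
}
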