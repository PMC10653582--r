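#' Read a multiple sequence alignment
#'
#' Reads FASTA, A3M or Stockholm alignments into a query-anchored
#' [Alignment]: the first record is taken as the query, A3M lowercase
#' letters (insertion states not matched to the query) are removed,
#' Stockholm `.` is treated as a gap, and columns in which the query has a
#' gap are dropped, so that every matrix column corresponds to a query
#' position. After reading, the alignment may still contain the ambiguity
#' codes X/U/B/Z; run [preprocess_undefined()] before downstream analysis.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"`, `"a3m"` or `"stockholm"`. Defaults to a guess
#'   from the file extension.
#' @param taxon taxon label stored on the alignment (see [new_alignment()]).
#' @param source_protocol provenance tag stored on the alignment.
#' @return an [Alignment].
#' @export
read_alignment <- function(path,
                           format = c("fasta", "a3m", "stockholm"),
                           taxon = "unknown",
                           source_protocol = "unknown") {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     a3m = "a3m",
                     sto = , stk = , stockholm = "stockholm",
                     "fasta")
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "stockholm") {
    msa <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "stockholm"),
      error = function(e) stop("Stockholm parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    seqs <- as.character(msa@unmasked)
    if (length(seqs) == 0L) stop("no records in ", path, call. = FALSE)
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    chars <- strsplit(toupper(seqs), "", fixed = TRUE)
    chars <- lapply(chars, function(x) { x[x == "."] <- GAP; x })
    lens <- lengths(chars)
    if (length(unique(lens)) != 1L)
      stop("ragged Stockholm alignment in ", path, call. = FALSE)
    mat <- do.call(rbind, chars)
  } else {
    # FASTA and A3M share the record structure; BStringSet accepts the
    # lowercase insertion letters A3M uses.
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("parse error in ", path, ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
    ids <- names(set)
    if (is.null(ids)) ids <- paste0("seq", seq_along(set))
    chars <- strsplit(as.character(set), "", fixed = TRUE)
    if (format == "a3m") {
      # lowercase = insertion relative to the query; drop those states
      chars <- lapply(chars, function(x) x[x == toupper(x)])
    }
    chars <- lapply(chars, function(x) {
      x <- toupper(x)
      x[x == "."] <- GAP
      x
    })
    lens <- lengths(chars)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths ",
           paste(unique(lens), collapse = ", "),
           if (format == "a3m") " after insertion removal",
           call. = FALSE)
    mat <- do.call(rbind, chars)
  }

  bad <- setdiff(unique(as.vector(mat)), c(AA_LETTERS, GAP, AMBIGUOUS))
  if (length(bad) > 0L)
    stop("non-IUPAC symbol(s) in ", path, ": ",
         paste(sort(bad), collapse = ", "), call. = FALSE)

  # anchor to the query: drop columns where the query row is gapped
  keep <- mat[1L, ] != GAP
  if (!any(keep)) stop("query row is entirely gaps in ", path, call. = FALSE)
  mat <- mat[, keep, drop = FALSE]

  new_alignment(mat, sequence_ids = ids, taxon = taxon,
                source_protocol = source_protocol, validate = FALSE)
}

#' Replace undefined residues by the column consensus
#'
#' Applies the preprocessing rule used before landscape prediction:
#' undefined residues (X, U, and the ambiguity codes B, Z) are replaced by
#' the most frequent canonical amino acid in their alignment column (gaps
#' excluded from the count; ties broken alphabetically). The one exception
#' is an undefined residue in the query whose column is otherwise all
#' gaps — such columns carry no information and are removed, shortening
#' the query. Every edit is recorded in a change log.
#'
#' @param aln an [Alignment], possibly containing X/U/B/Z.
#' @return a list with elements `alignment` (the cleaned [Alignment]),
#'   `changes` (data.frame with columns `row`, `position` (original
#'   1-based column), `old`, `new`), and `removed_columns` (original
#'   1-based indices of deleted columns). The operation is idempotent.
#' @export
preprocess_undefined <- function(aln) {
  mat <- aln$matrix
  n <- nrow(mat)
  L <- ncol(mat)
  changes <- list()
  drop_cols <- integer(0)

  for (j in seq_len(L)) {
    col <- mat[, j]
    amb <- which(col %in% AMBIGUOUS)
    if (length(amb) == 0L) next
    below <- if (n > 1L) col[-1L] else character(0)
    if (col[1L] %in% AMBIGUOUS && all(below == GAP)) {
      # undefined query residue over an all-gap column: no evidence, drop
      drop_cols <- c(drop_cols, j)
      next
    }
    counts <- table(factor(col[col %in% AA_LETTERS], levels = AA_LETTERS))
    if (sum(counts) == 0L)
      stop("unresolvable column ", j,
           ": only gaps and undefined symbols present", call. = FALSE)
    consensus <- AA_LETTERS[which.max(counts)]  # alphabetical tie-break
    for (s in amb) {
      changes[[length(changes) + 1L]] <-
        data.frame(row = s, position = j, old = col[s], new = consensus,
                   stringsAsFactors = FALSE)
      mat[s, j] <- consensus
    }
  }

  if (length(drop_cols) > 0L) mat <- mat[, -drop_cols, drop = FALSE]
  if (ncol(mat) == 0L)
    stop("alignment empty after removing undefined all-gap columns",
         call. = FALSE)

  changes <- if (length(changes) > 0L) do.call(rbind, changes) else
    data.frame(row = integer(0), position = integer(0),
               old = character(0), new = character(0))

  out <- new_alignment(mat, sequence_ids = aln$sequence_ids,
                       taxon = aln$taxon,
                       source_protocol = aln$source_protocol,
                       validate = FALSE)
  validate_alignment(out, strict = TRUE)
  list(alignment = out, changes = changes, removed_columns = drop_cols)
}

#' Minimum-length gate for query sequences
#'
#' Very short queries (20 residues or fewer, by default) are not treated
#' as proteins and are skipped by the pipeline.
#'
#' @param aln a preprocessed [Alignment].
#' @param min_len skip threshold: verdict is `"skip"` iff the query length
#'   is `<= min_len`. Default 20.
#' @return `"pass"` or `"skip"`.
#' @export
check_query_length <- function(aln, min_len = 20L) {
  if (alignment_length(aln) <= min_len) "skip" else "pass"
}
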