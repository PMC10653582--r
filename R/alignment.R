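# Canonical one-letter amino-acid alphabet, alphabetical order.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"
AMBIGUOUS <- c("X", "U", "B", "Z")
TAXA <- c("human", "eukaryote", "prokaryote", "virus", "unknown")

#' Construct a query-anchored alignment object
#'
#' An `Alignment` is the container every other function in the package
#' operates on: an N x L character matrix over the 20 amino acids plus the
#' gap symbol `-`, whose first row is the query sequence. Columns always
#' correspond to query positions (columns in which the query had a gap are
#' removed when files are read), so position `i` of the matrix is position
#' `i` of the query.
#'
#' @param matrix character matrix (N x L) of single-letter symbols; row 1
#'   is the query.
#' @param sequence_ids character vector of length N.
#' @param taxon one of `"human"`, `"eukaryote"`, `"prokaryote"`, `"virus"`,
#'   `"unknown"`. Drives the default sequence-identity threshold used in
#'   weighting (see [default_theta()]).
#' @param source_protocol free-text tag recording where the alignment came
#'   from (e.g. `"colabfold"`, `"jackhmmer"`, `"simulated"`).
#' @param validate check invariants (symbols, query gaps). Preprocessing
#'   functions construct intermediate alignments with `validate = FALSE`.
#' @return an object of class `Alignment`.
#' @export
new_alignment <- function(matrix, sequence_ids = NULL,
                          taxon = "unknown", source_protocol = "unknown",
                          validate = TRUE) {
  if (!is.matrix(matrix) || !is.character(matrix))
    stop("`matrix` must be a character matrix", call. = FALSE)
  if (nrow(matrix) < 1L || ncol(matrix) < 1L)
    stop("alignment must have at least one sequence and one column",
         call. = FALSE)
  if (is.null(sequence_ids))
    sequence_ids <- paste0("seq", seq_len(nrow(matrix)))
  if (length(sequence_ids) != nrow(matrix))
    stop("`sequence_ids` length must equal the number of rows", call. = FALSE)
  taxon <- match.arg(taxon, TAXA)
  aln <- structure(
    list(query_id = sequence_ids[[1L]],
         sequence_ids = as.character(sequence_ids),
         matrix = unname(matrix),
         taxon = taxon,
         source_protocol = source_protocol),
    class = "Alignment")
  if (validate) validate_alignment(aln, strict = FALSE)
  aln
}

# strict = TRUE additionally requires the post-preprocessing invariants:
# no ambiguity codes anywhere and a gap-free query row.
validate_alignment <- function(aln, strict = TRUE) {
  allowed <- c(AA_LETTERS, GAP, if (!strict) AMBIGUOUS)
  bad <- setdiff(unique(as.vector(aln$matrix)), allowed)
  if (length(bad) > 0L)
    stop("invalid alignment symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (strict && any(aln$matrix[1L, ] == GAP))
    stop("query row contains gaps after preprocessing", call. = FALSE)
  invisible(aln)
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d positions\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  query: %s\n  taxon: %s  source: %s\n",
              x$query_id, x$taxon, x$source_protocol))
  invisible(x)
}

#' @export
dim.Alignment <- function(x) dim(x$matrix)

#' Number of sequences / alignment length
#' @param aln an [Alignment].
#' @return integer.
#' @export
n_sequences <- function(aln) nrow(aln$matrix)

#' @rdname n_sequences
#' @export
alignment_length <- function(aln) ncol(aln$matrix)

#' Query sequence of an alignment
#' @param aln an [Alignment].
#' @param collapse return a single string rather than a character vector.
#' @return the query row.
#' @export
query_sequence <- function(aln, collapse = FALSE) {
  q <- aln$matrix[1L, ]
  if (collapse) paste(q, collapse = "") else q
}

#' Write an alignment to FASTA or Stockholm
#'
#' Inverse of [read_alignment()] for the gapped formats: a read-write-read
#' round trip reproduces the matrix exactly.
#'
#' @param aln an [Alignment].
#' @param path output file path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  if (format == "fasta") {
    set <- Biostrings::BStringSet(seqs)
    names(set) <- aln$sequence_ids
    Biostrings::writeXStringSet(set, filepath = path)
  } else {
    ids <- make.unique(aln$sequence_ids)
    pad <- max(nchar(ids))
    lines <- c("# STOCKHOLM 1.0",
               sprintf("%-*s %s", pad, ids, seqs),
               "//")
    writeLines(lines, path)
  }
  invisible(path)
}
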