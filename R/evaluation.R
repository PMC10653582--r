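#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties — the accuracy metric
#' used throughout the evaluation protocol. A constant input has no rank
#' ordering, so the correlation is undefined and an error is raised
#' (callers report the result as missing, never as 0).
#'
#' @param pred,obs numeric vectors of equal length `>= 2`.
#' @return a real in `[-1, 1]`.
#' @export
spearman_rho <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("inputs have different lengths", call. = FALSE)
  if (length(pred) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  if (length(unique(pred)) == 1L || length(unique(obs)) == 1L)
    stop("undefined correlation: constant input vector", call. = FALSE)
  stats::cor(pred, obs, method = "spearman")
}

#' Read a DMS score table
#'
#' Reads a ProteinGym-style CSV with a `mutant` column (strings such as
#' `"A25G"` or `"A25G:F33L"`) and a named measurement column. Higher
#' measurement is assumed to mean more functional; use `flip = TRUE` for
#' assays where lower is better.
#'
#' @param path CSV path.
#' @param measurement name of the measurement column.
#' @param experiment_id,target_id,taxon metadata stored on the table.
#' @param flip negate the measurements.
#' @return an object of class `DMSTable` (a data.frame with columns
#'   `mutant`, `measurement`, plus metadata attributes).
#' @export
read_dms <- function(path, measurement = "DMS_score",
                     experiment_id = basename(path),
                     target_id = experiment_id,
                     taxon = "unknown", flip = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("mutant" %in% names(df)))
    stop("DMS table must have a `mutant` column", call. = FALSE)
  if (!(measurement %in% names(df)))
    stop("measurement column not found: ", measurement, call. = FALSE)
  dms_table(df$mutant, df[[measurement]],
            experiment_id = experiment_id, target_id = target_id,
            taxon = taxon, flip = flip)
}

#' @rdname read_dms
#' @param mutants character vector of mutant strings.
#' @param measurements numeric vector of the same length.
#' @export
dms_table <- function(mutants, measurements, experiment_id = "dms",
                      target_id = experiment_id, taxon = "unknown",
                      flip = FALSE) {
  if (anyDuplicated(mutants))
    stop("duplicate mutant string(s): ",
         paste(unique(mutants[duplicated(mutants)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(measurements)))
    stop("non-finite measurement(s)", call. = FALSE)
  out <- data.frame(mutant = as.character(mutants),
                    measurement = if (flip) -measurements else measurements,
                    stringsAsFactors = FALSE)
  structure(out,
            experiment_id = experiment_id, target_id = target_id,
            taxon = taxon,
            multiple_mutants = any(grepl(":", mutants, fixed = TRUE)),
            class = c("DMSTable", "data.frame"))
}

#' Evaluate a landscape against a DMS experiment
#'
#' Scores every parseable variant with [combined_score()] and returns
#' the Spearman correlation between predictions and measurements.
#' When a `region` of query positions is given (to restrict comparisons
#' to the positions two protocols have in common), variants touching any
#' position outside it are excluded and counted.
#'
#' @param landscape a `Landscape`.
#' @param dms a `DMSTable`.
#' @param region optional integer vector of query positions to keep.
#' @param offset numbering offset passed to [parse_mutant()].
#' @param depth_class optional depth-class label carried into the result.
#' @return an object of class `EvaluationResult` with fields `rho`,
#'   `n_variants`, `n_excluded`, `position_range`, `experiment_id`,
#'   `target_id`, `taxon`, `depth_class`.
#' @export
evaluate_landscape <- function(landscape, dms, region = NULL, offset = 0L,
                               depth_class = NA_character_) {
  if (!is.null(region)) {
    region <- as.integer(region)
    if (!all(region %in% landscape$positions))
      stop("region contains positions outside the landscape", call. = FALSE)
  }
  preds <- rep(NA_real_, nrow(dms))
  used_positions <- integer(0)
  excluded <- character(0)
  for (r in seq_len(nrow(dms))) {
    sq <- tryCatch(parse_mutant(dms$mutant[[r]], landscape$wildtype,
                                offset = offset),
                   error = function(e) NULL)
    if (is.null(sq)) { excluded <- c(excluded, dms$mutant[[r]]); next }
    if (!is.null(region) && !all(sq$position %in% region)) {
      excluded <- c(excluded, dms$mutant[[r]]); next
    }
    preds[r] <- combined_score(landscape, sq)
    used_positions <- c(used_positions, sq$position)
  }
  keep <- !is.na(preds)
  if (sum(keep) < 2L)
    stop("insufficient data: fewer than 2 scoreable variants", call. = FALSE)
  rho <- tryCatch(spearman_rho(preds[keep], dms$measurement[keep]),
                  error = function(e) NA_real_)
  structure(
    list(experiment_id = attr(dms, "experiment_id"),
         target_id = attr(dms, "target_id"),
         taxon = attr(dms, "taxon"),
         depth_class = depth_class,
         rho = rho,
         n_variants = sum(keep),
         n_excluded = length(excluded),
         excluded = excluded,
         position_range = range(used_positions)),
    class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf(
    "EvaluationResult [%s]: rho = %.3f over %d variants (%d excluded)\n",
    x$experiment_id, x$rho, x$n_variants, x$n_excluded))
  invisible(x)
}

#' Aggregate evaluation results
#'
#' Two-stage averaging: experiments are first averaged within each
#' target protein, then target means are averaged within each group
#' (defined by `by`: any subset of `taxon` and `depth_class`). The flat
#' per-experiment mean is also reported, since class summaries can be
#' weighted either by protein or by experiment. When results carry a
#' `protocol` label and exactly two protocols are present, the per-group
#' mean difference (delta rho) over paired targets is included.
#'
#' @param results list of `EvaluationResult`s; entries may carry an
#'   optional `protocol` field for paired comparisons.
#' @param by grouping keys, subset of `c("taxon", "depth_class")`;
#'   empty for a single overall group.
#' @return a list with data.frames `per_experiment`, `per_target`, and
#'   `groups` (columns: group keys, `mean_rho_by_target`,
#'   `mean_rho_by_dms`, `n_targets`, `n_dms`, and `delta_rho` for paired
#'   protocols).
#' @export
aggregate_results <- function(results, by = character(0)) {
  if (length(results) == 0L) stop("no results to aggregate", call. = FALSE)
  stopifnot(all(by %in% c("taxon", "depth_class")))
  per_exp <- do.call(rbind, lapply(results, function(r)
    data.frame(experiment_id = r$experiment_id,
               target_id = r$target_id,
               taxon = r$taxon,
               depth_class = r$depth_class,
               protocol = if (!is.null(r$protocol)) r$protocol else "default",
               rho = r$rho,
               n_variants = r$n_variants,
               stringsAsFactors = FALSE)))
  per_exp <- per_exp[!is.na(per_exp$rho), , drop = FALSE]

  key_of <- function(df) {
    if (length(by) == 0L) rep("all", nrow(df)) else
      do.call(paste, c(df[by], sep = "|"))
  }

  # stage 1: mean over a target's experiments (within protocol)
  per_target <- stats::aggregate(
    rho ~ target_id + protocol + taxon + depth_class, data = per_exp,
    FUN = mean)
  names(per_target)[names(per_target) == "rho"] <- "mean_rho"

  # stage 2: mean over targets within group
  split_groups <- function(df, value_col) {
    k <- key_of(df)
    vapply(split(df[[value_col]], k), mean, numeric(1))
  }

  protocols <- unique(per_exp$protocol)
  groups_list <- list()
  for (p in protocols) {
    pt <- per_target[per_target$protocol == p, , drop = FALSE]
    pe <- per_exp[per_exp$protocol == p, , drop = FALSE]
    g_target <- split_groups(pt, "mean_rho")
    g_dms <- split_groups(pe, "rho")
    n_targets <- vapply(split(pt$target_id, key_of(pt)),
                        function(x) length(unique(x)), integer(1))
    n_dms <- table(key_of(pe))
    groups_list[[p]] <- data.frame(
      group = names(g_target),
      protocol = p,
      mean_rho_by_target = as.numeric(g_target),
      mean_rho_by_dms = as.numeric(g_dms[names(g_target)]),
      n_targets = as.integer(n_targets[names(g_target)]),
      n_dms = as.integer(n_dms[names(g_target)]),
      stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, groups_list)
  rownames(groups) <- NULL

  delta <- NULL
  if (length(protocols) == 2L) {
    a <- per_target[per_target$protocol == protocols[[1L]], ]
    b <- per_target[per_target$protocol == protocols[[2L]], ]
    orphans <- c(setdiff(a$target_id, b$target_id),
                 setdiff(b$target_id, a$target_id))
    if (length(orphans) > 0L)
      stop("unpaired target(s) across protocols: ",
           paste(orphans, collapse = ", "), call. = FALSE)
    m <- merge(a, b, by = "target_id", suffixes = c("_a", "_b"))
    m$diff <- m$mean_rho_a - m$mean_rho_b
    k <- if (length(by) == 0L) rep("all", nrow(m)) else
      do.call(paste, c(m[paste0(by, "_a")], sep = "|"))
    delta <- data.frame(
      group = names(split(m$diff, k)),
      delta_rho = vapply(split(m$diff, k), mean, numeric(1)),
      comparison = paste(protocols[[1L]], "-", protocols[[2L]]),
      stringsAsFactors = FALSE)
    rownames(delta) <- NULL
  }

  list(per_experiment = per_exp, per_target = per_target,
       groups = groups, delta = delta)
}

#' Greedy redundancy filter over benchmark sequences
#'
#' Removes near-duplicate proteins from a benchmark set given
#' precomputed pairwise alignment records. A pair is redundant when its
#' identity reaches the threshold — except that alignments shorter than
#' 50 residues between two sequences that are both at least 180 residues
#' long are ignored, so that incidental short local matches cannot knock
#' out long proteins. Ids are retained greedily in input order; an id is
#' dropped when redundant with an already-retained id.
#'
#' @param ids candidate sequence ids, in priority order.
#' @param pairwise data.frame with columns `idA`, `idB`,
#'   `alignment_length`, `identity` (fraction in `[0, 1]`), `lenA`,
#'   `lenB`.
#' @param threshold identity cutoff at or above which a (non-exempt)
#'   pair is redundant.
#' @param min_aln_len,min_seq_len parameters of the short-alignment
#'   exemption (defaults 50 and 180).
#' @return the retained ids, in input order.
#' @export
redundancy_filter <- function(ids, pairwise, threshold,
                              min_aln_len = 50L, min_seq_len = 180L) {
  needed <- c("idA", "idB", "alignment_length", "identity", "lenA", "lenB")
  stopifnot(all(needed %in% names(pairwise)),
            all(pairwise$lenA > 0), all(pairwise$lenB > 0))
  redundant_pair <- pairwise$identity >= threshold &
    !(pairwise$alignment_length < min_aln_len &
        pmin(pairwise$lenA, pairwise$lenB) >= min_seq_len)
  red <- pairwise[redundant_pair, , drop = FALSE]
  retained <- character(0)
  for (id in ids) {
    clash <- (red$idA == id & red$idB %in% retained) |
      (red$idB == id & red$idA %in% retained)
    if (!any(clash)) retained <- c(retained, id)
  }
  retained
}
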