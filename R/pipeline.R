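#' Build a run configuration
#'
#' Collects every knob of the preprocess -> depth -> conserve -> predict
#' -> evaluate pipeline into one serializable list. The resolved
#' configuration is written beside each run's outputs, and re-running
#' from that file reproduces the run byte for byte.
#'
#' @param msa path to the input alignment.
#' @param format alignment format (`"fasta"`, `"a3m"`, `"stockholm"`).
#' @param taxon taxon label (drives the default theta_id).
#' @param theta_id override for the weighting threshold; `NULL` uses the
#'   taxon default.
#' @param min_query_len queries of this length or shorter are skipped
#'   (default 20).
#' @param shallow_msa_threshold alignments with fewer sequences than
#'   this trigger the advisory to regenerate the MSA without the
#'   search-stage filter (default 200).
#' @param linkage tree linkage for conservation.
#' @param kappa,lambda,alpha landscape parameters
#'   (see [single_landscape()]).
#' @param dms optional DMS CSV path; `measurement` names its score
#'   column; `flip` negates it.
#' @param region optional integer positions to restrict evaluation to.
#' @param offset mutation-numbering offset.
#' @param out_dir output directory.
#' @param seed seed recorded with the run.
#' @return a `RunConfig` list.
#' @export
run_config <- function(msa, format = "fasta", taxon = "unknown",
                       theta_id = NULL, min_query_len = 20L,
                       shallow_msa_threshold = 200L,
                       linkage = "average", kappa = 0.2, lambda = 1,
                       alpha = 0, dms = NULL, measurement = "DMS_score",
                       flip = FALSE, region = NULL, offset = 0L,
                       out_dir = NULL, seed = 1L) {
  structure(list(msa = msa, format = format, taxon = taxon,
                 theta_id = theta_id, min_query_len = min_query_len,
                 shallow_msa_threshold = shallow_msa_threshold,
                 linkage = linkage, kappa = kappa, lambda = lambda,
                 alpha = alpha, dms = dms, measurement = measurement,
                 flip = flip, region = region, offset = offset,
                 out_dir = out_dir, seed = seed),
            class = "RunConfig")
}

#' Read / write a run configuration
#' @param path YAML file path.
#' @return a `RunConfig` ([read_config()]) or `path` ([write_config()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$region <- if (!is.null(cfg$region)) as.integer(cfg$region)
  do.call(run_config, cfg)
}

#' @rdname read_config
#' @param config a `RunConfig`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[mutland] %s", sprintf(fmt, ...)))
}

#' Run the full prediction pipeline
#'
#' Executes preprocess -> depth -> conservation -> landscape (->
#' evaluation when a DMS table is configured) and writes all outputs and
#' the resolved configuration to `out_dir`. Runs are deterministic:
#' identical config and inputs give byte-identical landscape files.
#'
#' Two policy gates are applied. Queries of `min_query_len` residues or
#' fewer are skipped outright (too short to be treated as proteins), and
#' alignments with fewer than `shallow_msa_threshold` sequences complete
#' normally but carry an advisory to regenerate the MSA without the
#' search-stage filter, which typically deepens sparse families.
#'
#' @param config a `RunConfig` from [run_config()] or [read_config()].
#' @param quiet suppress progress messages.
#' @return a run report (list): `status` (`"ok"` or `"skipped"`),
#'   `verdicts`, `advisories`, `depth`, `conservation`, `landscape`,
#'   `evaluation` (when configured), `outputs` (paths written) and
#'   `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  out_dir <- config$out_dir
  outputs <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    outputs$config <- file.path(out_dir, "config.yaml")
  }
  report <- list(status = "ok", verdicts = list(), advisories = character(0),
                 config = config, outputs = outputs)

  stage <- "preprocess"
  run_stages <- function() {
    log_stage(quiet, "reading %s (%s)", config$msa, config$format)
    aln <- read_alignment(config$msa, format = config$format,
                          taxon = config$taxon)
    pre <- preprocess_undefined(aln)
    aln <- pre$alignment
    report$verdicts$n_undefined_edits <- nrow(pre$changes)
    report$verdicts$removed_columns <- pre$removed_columns

    verdict <- check_query_length(aln, config$min_query_len)
    report$verdicts$query_length <- verdict
    if (verdict == "skip") {
      report$status <- "skipped"
      report$verdicts$reason <-
        sprintf("query length %d <= min_query_len %d",
                alignment_length(aln), config$min_query_len)
      log_stage(quiet, "skipped: %s", report$verdicts$reason)
      return(report)
    }
    if (n_sequences(aln) < config$shallow_msa_threshold) {
      report$advisories <- c(report$advisories, sprintf(
        "MSA has %d sequences (< %d): consider regenerating it without the search-stage filter",
        n_sequences(aln), config$shallow_msa_threshold))
    }

    stage <<- "depth"
    theta <- if (!is.null(config$theta_id)) config$theta_id else
      default_theta(config$taxon)
    dep <- depth_report(aln, theta_id = theta)
    report$depth <- dep
    log_stage(quiet, "depth: Neff %.1f, class %s", dep$neff,
              dep$depth_class)

    stage <<- "conservation"
    cons <- conservation_profile(aln, linkage = config$linkage)
    report$conservation <- cons

    stage <<- "predict"
    freqs <- reduced_frequencies(aln, weights = dep$weights,
                                 lambda = config$lambda)
    scape <- single_landscape(aln, cons = cons, freqs = freqs,
                              kappa = config$kappa,
                              lambda = config$lambda,
                              alpha = config$alpha)
    report$landscape <- scape
    if (!is.null(out_dir)) {
      wide <- file.path(out_dir, "landscape_wide.tsv")
      long <- file.path(out_dir, "landscape_long.csv")
      write_landscape(scape, wide = wide, long = long)
      cons_tsv <- file.path(out_dir, "conservation.tsv")
      utils::write.table(
        data.frame(position = seq_along(cons$levels),
                   residue = query_sequence(aln),
                   level = cons$levels),
        cons_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
      depth_json <- file.path(out_dir, "depth.json")
      jsonlite::write_json(
        dep[c("neff", "L", "Lcov", "ratio_L", "ratio_Lcov", "theta_id",
              "depth_class")],
        depth_json, auto_unbox = TRUE, digits = NA)
      report$outputs <- c(report$outputs,
                          list(landscape_wide = wide, landscape_long = long,
                               conservation = cons_tsv, depth = depth_json))
    }

    if (!is.null(config$dms)) {
      stage <<- "evaluate"
      dms <- read_dms(config$dms, measurement = config$measurement,
                      flip = config$flip)
      ev <- evaluate_landscape(scape, dms, region = config$region,
                               offset = config$offset,
                               depth_class = dep$depth_class)
      report$evaluation <- ev
      log_stage(quiet, "evaluation: rho %.3f over %d variants", ev$rho,
                ev$n_variants)
      if (!is.null(out_dir)) {
        eval_json <- file.path(out_dir, "evaluation.json")
        jsonlite::write_json(
          ev[c("experiment_id", "rho", "n_variants", "n_excluded",
               "depth_class", "taxon")],
          eval_json, auto_unbox = TRUE, digits = NA)
        report$outputs$evaluation <- eval_json
      }
    }
    report
  }
  result <- tryCatch(run_stages(), error = function(e) {
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) {
    summary <- list(status = result$status,
                    verdicts = result$verdicts,
                    advisories = result$advisories,
                    depth_class = if (!is.null(result$depth))
                      result$depth$depth_class,
                    rho = if (!is.null(result$evaluation))
                      result$evaluation$rho)
    jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
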