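# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic protein family
#'
#' Bundles the parameters of the sequence-evolution simulator: family
#' size, sequence length, a pure-birth (Yule) tree shape, per-site
#' constraint, and the noise level of matched synthetic deep
#' mutational scans. Site i's constraint `kappa[i]` in `[0, 1]` is the
#' probability that a proposed substitution at that site is rejected:
#' `kappa = 1` freezes the site, `kappa = 0` lets it drift freely.
#'
#' @param n_sequences number of leaves (sequences) in the family.
#' @param length sequence length L.
#' @param birth_rate speciation rate of the pure-birth tree.
#' @param kappa per-site constraint vector (recycled to length L);
#'   default: sites drawn uniformly on `[0, 1]`.
#' @param branch_scale multiplier on branch lengths: expected number of
#'   substitution proposals per site per unit branch length.
#' @param effect_size scale of the true mutation effects in synthetic
#'   DMS tables.
#' @param dms_noise_sd Gaussian noise SD added to synthetic DMS
#'   measurements.
#' @param seed integer seed; a fixed seed makes every output
#'   byte-identical across runs.
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_sequences = 100L, length = 50L,
                           birth_rate = 1, kappa = NULL,
                           branch_scale = 1, effect_size = 1,
                           dms_noise_sd = 0.1, seed = 1L) {
  stopifnot(n_sequences >= 1L, length >= 1L, birth_rate > 0,
            branch_scale >= 0, dms_noise_sd >= 0)
  if (!is.null(kappa)) {
    kappa <- rep_len(kappa, length)
    stopifnot(all(kappa >= 0), all(kappa <= 1))
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length),
                 birth_rate = birth_rate,
                 kappa = kappa,
                 branch_scale = branch_scale,
                 effect_size = effect_size,
                 dms_noise_sd = dms_noise_sd,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Simulate an alignment with known site constraints
#'
#' Evolves sequences down a simulated pure-birth tree. The root sequence
#' (uniform over the 20 amino acids) is the query; along each branch,
#' each site receives a Poisson number of substitution proposals
#' (rate = branch length x `branch_scale`), each proposing a uniform
#' alternative residue that is rejected with probability `kappa[i]`.
#' Constrained sites therefore stay close to the root state and become
#' conserved columns; free sites drift. No indels are generated, so the
#' alignment is gap-free.
#'
#' @param spec a `SyntheticSpec`.
#' @return a list with `alignment` (an [Alignment]; row 1 = root/query),
#'   `tree` (the true `phylo` tree), and `kappa` (the realized per-site
#'   constraint vector). Deterministic given `spec$seed`.
#' @export
simulate_msa <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, {
    L <- spec$length
    n <- spec$n_sequences
    kappa <- if (is.null(spec$kappa)) stats::runif(L) else spec$kappa
    root <- sample(AA_LETTERS, L, replace = TRUE)

    if (n == 1L) {
      mat <- matrix(root, nrow = 1L)
      aln <- new_alignment(mat, sequence_ids = "query",
                           source_protocol = "simulated")
      return(list(alignment = aln, tree = NULL, kappa = kappa))
    }

    phy <- ape::rphylo(n, birth = spec$birth_rate, death = 0)
    # cladewise edge order visits every parent before its children
    phy <- stats::reorder(phy, "cladewise")
    edges <- phy$edge
    lens <- phy$edge.length
    n_nodes <- max(phy$edge)
    seqs <- vector("list", n_nodes)
    root_node <- n + 1L
    seqs[[root_node]] <- root
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1L]
      child <- edges[e, 2L]
      s <- seqs[[parent]]
      n_prop <- stats::rpois(L, lens[e] * spec$branch_scale)
      for (i in which(n_prop > 0L)) {
        for (p in seq_len(n_prop[i])) {
          cand <- sample(setdiff(AA_LETTERS, s[i]), 1L)
          if (stats::runif(1) >= kappa[i]) s[i] <- cand
        }
      }
      seqs[[child]] <- s
    }
    tip_seqs <- do.call(rbind, seqs[seq_len(n)])
    mat <- rbind(root, tip_seqs)
    ids <- c("query", phy$tip.label)
    aln <- new_alignment(mat, sequence_ids = ids,
                         source_protocol = "simulated")
    list(alignment = aln, tree = phy, kappa = kappa)
  })
}

#' Simulate a matched DMS experiment
#'
#' Generates a synthetic deep-mutational-scanning table for the family's
#' query: each sampled single substitution at site i measures
#' `-kappa[i] * effect_size` plus Gaussian noise, so constrained sites
#' read out as deleterious. Multi-mutant rows (optional) are sums of
#' their singles plus one noise draw.
#'
#' @param sim output of [simulate_msa()] (for the query and `kappa`).
#' @param spec the `SyntheticSpec` (noise SD, effect size, seed).
#' @param n_variants number of single-substitution variants to sample
#'   (without replacement over the L x 19 possibilities).
#' @param n_multi number of double mutants to add.
#' @param seed seed for the DMS draw; default `spec$seed + 1`.
#' @return a `DMSTable`.
#' @export
simulate_dms <- function(sim, spec, n_variants = 500L, n_multi = 0L,
                         seed = spec$seed + 1L) {
  kappa <- sim$kappa
  q <- query_sequence(sim$alignment)
  L <- length(q)
  with_seed(seed, {
    grid <- expand.grid(pos = seq_len(L), mut = AA_LETTERS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[q[grid$pos] != grid$mut, ]
    n_variants <- min(n_variants, nrow(grid))
    pick <- grid[sample.int(nrow(grid), n_variants), ]
    mutants <- paste0(q[pick$pos], pick$pos, pick$mut)
    truth <- -kappa[pick$pos] * spec$effect_size
    meas <- truth + stats::rnorm(n_variants, sd = spec$dms_noise_sd)

    if (n_multi > 0L && L >= 2L) {
      for (k in seq_len(n_multi)) {
        pos2 <- sample.int(L, 2L)
        mut2 <- vapply(pos2, function(p)
          sample(setdiff(AA_LETTERS, q[p]), 1L), character(1))
        mname <- paste0(q[pos2], pos2, mut2, collapse = ":")
        if (mname %in% mutants) next
        mutants <- c(mutants, mname)
        meas <- c(meas,
                  sum(-kappa[pos2] * spec$effect_size) +
                    stats::rnorm(1, sd = spec$dms_noise_sd))
      }
    }
    dms_table(mutants, meas, experiment_id = "synthetic_dms",
              target_id = "synthetic_target", taxon = "unknown")
  })
}

#' Preset families for the three alignment-depth regimes
#'
#' Returns `SyntheticSpec`s whose realized Neff/Lcov falls below 1
#' (`low`), between 1 and 100 (`medium`), and above 100 (`high`). Each
#' preset is verified at generation time by simulating the family and
#' measuring its depth; a preset landing outside its regime raises an
#' error (re-seed to resolve).
#'
#' @param seed base seed; the three presets use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param verify simulate each preset and check its realized ratio.
#' @return named list of `SyntheticSpec`s (`low`, `medium`, `high`).
#' @export
depth_regimes <- function(seed = 1L, verify = TRUE) {
  specs <- list(
    # near-duplicate family: Neff collapses to ~1, far below Lcov
    low = synthetic_spec(n_sequences = 40L, length = 80L,
                         branch_scale = 0.02, seed = seed),
    # moderately divergent family of typical size
    medium = synthetic_spec(n_sequences = 150L, length = 40L,
                            branch_scale = 2, kappa = 0,
                            seed = seed + 1L),
    # very many divergent sequences over a short region
    high = synthetic_spec(n_sequences = 1500L, length = 12L,
                          branch_scale = 4, kappa = 0,
                          seed = seed + 2L))
  if (verify) {
    bounds <- list(low = c(0, 1), medium = c(1, 100), high = c(100, Inf))
    for (nm in names(specs)) {
      sim <- simulate_msa(specs[[nm]])
      rep <- depth_report(sim$alignment)
      r <- rep$ratio_Lcov
      if (!(r > bounds[[nm]][1L] && r < bounds[[nm]][2L]))
        stop("preset `", nm, "` realized Neff/Lcov = ", signif(r, 4),
             ", outside its regime; re-seed", call. = FALSE)
    }
  }
  specs
}
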