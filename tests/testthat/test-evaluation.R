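test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(spearman_rho(1:5, 2 * (1:5) + 3), 1)
  expect_equal(spearman_rho(1:5, rev(1:5)), -1)

  pred <- c(1, 2, 2, 4)
  obs <- c(10, 20, 20, 40)
  expect_equal(spearman_rho(pred, obs), oracle_spearman(pred, obs))

  set.seed(501)
  for (r in 1:10) {
    x <- sample(1:8, 20, replace = TRUE)   # plenty of ties
    y <- sample(1:8, 20, replace = TRUE)
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  }
})

test_that("Spearman is invariant under strictly increasing transforms", {
  set.seed(502)
  x <- rnorm(30)
  y <- rnorm(30)
  rho <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), rho)
  expect_equal(spearman_rho(x, y^3 + 5 * y), rho)
})

test_that("constant inputs raise an undefined-correlation error", {
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:5, rep(2, 5)), "constant")
  expect_error(spearman_rho(1, 1), "at least 2")
})

test_that("DMS tables reject duplicates and can flip their sign", {
  expect_error(dms_table(c("A1G", "A1G"), c(1, 2)), "duplicate")
  expect_error(dms_table(c("A1G", "A2G"), c(1, NA)), "finite")
  tab <- dms_table(c("A1G", "A2G:A3G"), c(1, 2), flip = TRUE)
  expect_equal(tab$measurement, c(-1, -2))
  expect_true(attr(tab, "multiple_mutants"))
})

test_that("evaluation restricts to the requested region", {
  set.seed(503)
  aln <- random_alignment(15, 10, gap_prob = 0)
  scape <- single_landscape(aln)
  q <- scape$wildtype
  muts <- vapply(1:10, function(i)
    paste0(q[i], i, setdiff(AA20, q[i])[1]), character(1))
  dms <- dms_table(muts, rnorm(10))

  full <- evaluate_landscape(scape, dms)
  full_explicit <- evaluate_landscape(scape, dms, region = 1:10)
  expect_equal(full$rho, full_explicit$rho)
  expect_equal(full$n_variants, 10L)

  part <- evaluate_landscape(scape, dms, region = 1:9)
  expect_equal(part$n_variants, 9L)
  expect_equal(part$n_excluded, 1L)
  expect_equal(part$position_range, c(1L, 9L))

  expect_error(evaluate_landscape(scape, dms, region = 1:11), "outside")
})

test_that("unparseable variants are excluded, not scored", {
  set.seed(504)
  aln <- random_alignment(10, 8, gap_prob = 0)
  scape <- single_landscape(aln)
  q <- scape$wildtype
  good <- vapply(1:4, function(i)
    paste0(q[i], i, setdiff(AA20, q[i])[1]), character(1))
  dms <- dms_table(c(good, "Z99Q"), c(rnorm(4), 0))
  ev <- evaluate_landscape(scape, dms)
  expect_equal(ev$n_variants, 4L)
  expect_equal(ev$n_excluded, 1L)
  expect_equal(ev$excluded, "Z99Q")
})

test_that("fewer than two scoreable variants is an error", {
  set.seed(505)
  aln <- random_alignment(10, 8, gap_prob = 0)
  scape <- single_landscape(aln)
  q <- scape$wildtype
  dms <- dms_table(paste0(q[1], 1, setdiff(AA20, q[1])[1]), 1)
  expect_error(evaluate_landscape(scape, dms), "insufficient")
})

test_that("a noise-free monotone DMS correlates perfectly", {
  set.seed(506)
  aln <- random_alignment(20, 12, gap_prob = 0)
  scape <- single_landscape(aln)
  q <- scape$wildtype
  grid <- expand.grid(pos = 1:12, mut = AA20, stringsAsFactors = FALSE)
  grid <- grid[q[grid$pos] != grid$mut, ][1:100, ]
  muts <- paste0(q[grid$pos], grid$pos, grid$mut)
  scores <- vapply(muts, function(m) combined_score(scape, m), numeric(1))
  dms <- dms_table(muts, 3 * scores + 7)    # increasing transform
  ev <- evaluate_landscape(scape, dms)
  expect_equal(ev$rho, 1)
})

test_that("two-stage aggregation reproduces hand-computed means", {
  res <- function(exp, target, rho, taxon = "human", depth = "medium",
                  protocol = NULL) {
    r <- list(experiment_id = exp, target_id = target, taxon = taxon,
              depth_class = depth, rho = rho, n_variants = 50L,
              n_excluded = 0L, position_range = c(1L, 10L))
    if (!is.null(protocol)) r$protocol <- protocol
    structure(r, class = "EvaluationResult")
  }

  # one target with two experiments: target mean 0.5
  agg1 <- aggregate_results(list(res("e1", "t1", 0.4), res("e2", "t1", 0.6)))
  expect_equal(agg1$per_target$mean_rho, 0.5)
  expect_equal(agg1$groups$mean_rho_by_target, 0.5)

  # two targets (means 0.5, 0.7): group mean 0.6 by target,
  # flat per-DMS mean (0.4 + 0.6 + 0.7)/3
  agg2 <- aggregate_results(list(res("e1", "t1", 0.4), res("e2", "t1", 0.6),
                                 res("e3", "t2", 0.7)))
  expect_equal(agg2$groups$mean_rho_by_target, 0.6)
  expect_equal(agg2$groups$mean_rho_by_dms, mean(c(0.4, 0.6, 0.7)))

  # two-stage mean equals the flat mean when each target has one DMS
  agg3 <- aggregate_results(list(res("e1", "t1", 0.2), res("e2", "t2", 0.8)))
  expect_equal(agg3$groups$mean_rho_by_target, agg3$groups$mean_rho_by_dms)

  # grouping by taxon
  agg4 <- aggregate_results(
    list(res("e1", "t1", 0.2, taxon = "virus"),
         res("e2", "t2", 0.8, taxon = "human")), by = "taxon")
  expect_equal(nrow(agg4$groups), 2L)
  expect_equal(agg4$groups$mean_rho_by_target[agg4$groups$group == "virus"],
               0.2)
})

test_that("paired protocols give the mean per-target rho difference", {
  res <- function(target, rho, protocol) {
    structure(list(experiment_id = paste0(target, "_", protocol),
                   target_id = target, taxon = "human",
                   depth_class = "medium", rho = rho, n_variants = 50L,
                   n_excluded = 0L, position_range = c(1L, 10L),
                   protocol = protocol),
              class = "EvaluationResult")
  }
  results <- list(res("t1", 0.50, "p1"), res("t1", 0.40, "p2"),
                  res("t2", 0.70, "p1"), res("t2", 0.75, "p2"),
                  res("t3", 0.60, "p1"), res("t3", 0.30, "p2"))
  agg <- aggregate_results(results)
  expect_equal(agg$delta$delta_rho,
               mean(c(0.50 - 0.40, 0.70 - 0.75, 0.60 - 0.30)))

  orphaned <- c(results, list(res("t4", 0.5, "p1")))
  expect_error(aggregate_results(orphaned), "unpaired.*t4")
})

test_that("redundancy filter honors the short-alignment exemption", {
  pairs <- data.frame(
    idA = c("a", "c", "e"),
    idB = c("b", "d", "f"),
    alignment_length = c(40, 40, 300),
    identity = c(0.9, 0.9, 0.3),
    lenA = c(200, 100, 400),
    lenB = c(250, 300, 400))
  # a-b: 90% identity but a 40-residue alignment between two proteins
  # >= 180 long is exempt -> both kept
  # c-d: one protein is 100 long, exemption does not apply -> d dropped
  # e-f: identity below threshold -> both kept
  kept <- redundancy_filter(c("a", "b", "c", "d", "e", "f"), pairs,
                            threshold = 0.8)
  expect_equal(kept, c("a", "b", "c", "e", "f"))
})
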