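test_that("reduced-alphabet frequencies merge classes and honor weights", {
  leu <- new_alignment(matrix("L", 4, 1))
  f <- reduced_frequencies(leu, lambda = 0)
  expect_equal(unname(f$reduced[1, "ILV"]), 1)

  # D and E share the acidic class
  de <- new_alignment(matrix(c("D", "D", "E", "E"), 4, 1))
  f2 <- reduced_frequencies(de, lambda = 0)
  expect_equal(unname(f2$reduced[1, "DE"]), 1)

  # weighted counts: weights (1/2, 1/2, 1) over (D, D, K)
  dk <- new_alignment(matrix(c("D", "D", "K"), 3, 1))
  f3 <- reduced_frequencies(dk, weights = c(0.5, 0.5, 1), lambda = 0)
  expect_equal(unname(f3$reduced[1, "DE"]), 0.5)
  expect_equal(unname(f3$reduced[1, "KR"]), 0.5)
  expect_equal(unname(f3$full[1, "D"]), 0.5)
  expect_equal(unname(f3$full[1, "K"]), 0.5)
})

test_that("frequency rows normalize to one and pseudocounts smooth", {
  set.seed(401)
  aln <- random_alignment(10, 8)
  f <- reduced_frequencies(aln, lambda = 1)
  expect_equal(unname(rowSums(f$reduced)), rep(1, 8))
  expect_equal(unname(rowSums(f$full)), rep(1, 8))
  expect_true(all(f$reduced > 0))
})

test_that("gaps are excluded and all-gap columns warn with uniform output", {
  mat <- rbind(c("M", "K"), c("M", "-"), c("M", "-"))
  f <- reduced_frequencies(new_alignment(mat), lambda = 0)
  expect_equal(unname(f$full[2, "K"]), 1)   # only the non-gap symbol counts

  # a column with no residues at all (possible mid-preprocessing)
  allgap <- new_alignment(rbind(c("M", "-"), c("M", "-")), validate = FALSE)
  expect_warning(fg <- reduced_frequencies(allgap, lambda = 0), "all-gap")
  expect_equal(unname(fg$full[2, ]), rep(1 / 20, 20))
  expect_equal(unname(fg$reduced[2, ]), rep(1 / 11, 11))
})

test_that("evolutionary distance finds the cheapest witness", {
  # uniform conservation: a witness differing from the query only at i
  # sits at delta = 1/L
  aln <- aln_from_strings("AAAAAAAAAA",
                          "AAAAGAAAAA",
                          "CCCCGCCCCC")
  cons <- list(levels = rep(1, 10))
  expect_equal(evolutionary_distance(aln, cons, 5, "G"), 0.1)
  expect_equal(evolutionary_distance(aln, cons, 5, "A"), 0)  # wild type
  expect_true(is.na(evolutionary_distance(aln, cons, 5, "W")))
  expect_error(evolutionary_distance(aln, cons, 11, "A"), "range")
  expect_error(evolutionary_distance(aln, cons, 5, "-"), "canonical")
})

test_that("a query-only alignment yields one shared worst score", {
  aln <- new_alignment(do.call(rbind, replicate(4, c("M", "K", "V"),
                                                simplify = FALSE)))
  scape <- single_landscape(aln)
  wt_idx <- cbind(1:3, match(c("M", "K", "V"), scape$alphabet))
  expect_equal(unname(scape$scores[wt_idx]), rep(0, 3))
  non_wt <- scape$scores
  non_wt[wt_idx] <- NA
  vals <- non_wt[!is.na(non_wt)]
  expect_equal(unname(vals), rep(-1, length(vals)))
})

test_that("landscape normalization contracts hold", {
  set.seed(402)
  aln <- random_alignment(20, 12)
  scape <- single_landscape(aln)
  expect_equal(dim(scape$scores), c(12L, 20L))
  wt_idx <- cbind(1:12, match(scape$wildtype, scape$alphabet))
  expect_equal(unname(scape$scores[wt_idx]), rep(0, 12))
  expect_equal(min(scape$scores), -1)
  expect_true(all(scape$scores <= 0))
  expect_true(all(is.finite(scape$scores)))
})

test_that("observed tolerant substitutions beat unobserved conserved ones", {
  # position 2: low conservation, G observed near the query;
  # position 5: fully conserved column, W never observed
  aln <- aln_from_strings("AMAAKAAAAA",
                          "AGAAKAAAAA",
                          "AMCAKAACCA",
                          "ACACKACACC",
                          "AGCCKCCAAC")
  scape <- single_landscape(aln)
  g_at_2 <- scape$scores[2, "G"]
  w_at_5 <- scape$scores[5, "W"]
  expect_gt(g_at_2, w_at_5)
})

test_that("adding a witness never makes its substitution more deleterious", {
  set.seed(403)
  for (r in 1:5) {
    aln <- random_alignment(12, 10, gap_prob = 0)
    q <- query_sequence(aln)
    i <- sample(10, 1)
    b <- sample(setdiff(AA20, q[i]), 1)
    s0 <- single_landscape(aln)$scores[i, b]
    witness <- q
    witness[i] <- b
    aug <- new_alignment(rbind(aln$matrix, witness))
    s1 <- single_landscape(aug)$scores[i, b]
    expect_gte(s1, s0 - 1e-12)
  }
})

test_that("the landscape is invariant to homolog row order", {
  set.seed(404)
  aln <- random_alignment(15, 10)
  s0 <- single_landscape(aln)$scores
  perm <- c(1, 1 + sample(14))
  s1 <- single_landscape(new_alignment(aln$matrix[perm, ]))$scores
  expect_equal(s1, s0)
})

test_that("higher conservation gates scores downward at equal cost", {
  aln <- clade_fixture(include_free = FALSE)
  cons <- conservation_profile(aln)
  expect_gt(cons$levels[9], cons$levels[10])
  scape <- single_landscape(aln, cons = cons)
  non_wt <- setdiff(AA20, "A")
  expect_true(all(scape$scores[9, non_wt] <= scape$scores[10, non_wt] + 1e-12))
})

test_that("mutant strings parse, validate and respect offsets", {
  q <- strsplit("MKVLAG", "")[[1]]
  one <- parse_mutant("K2R", q)
  expect_equal(one$position, 2L)
  expect_equal(one$wt, "K")
  expect_equal(one$mut, "R")

  multi <- parse_mutant("K2R:L4F", q)
  expect_equal(nrow(multi), 2L)
  expect_equal(multi$position, c(2L, 4L))

  # DMS numbering shifted by +10 relative to the query
  shifted <- parse_mutant("K12R", q, offset = 10L)
  expect_equal(shifted$position, 2L)

  expect_error(parse_mutant("K2", q), "malformed")
  expect_error(parse_mutant("K9R", q), "range")
  expect_error(parse_mutant("A2R", q), "mismatch")
  expect_error(parse_mutant("K2R:K2W", q), "duplicate")
})

test_that("combined scores are additive over substitutions", {
  set.seed(405)
  aln <- random_alignment(15, 10, gap_prob = 0)
  scape <- single_landscape(aln)
  q <- scape$wildtype

  # synonymous substitution scores exactly zero
  syn <- paste0(q[3], 3, q[3])
  expect_equal(combined_score(scape, syn), 0)

  b2 <- setdiff(AA20, q[2])[1]
  b5 <- setdiff(AA20, q[5])[1]
  b8 <- setdiff(AA20, q[8])[1]
  singles <- c(combined_score(scape, paste0(q[2], 2, b2)),
               combined_score(scape, paste0(q[5], 5, b5)),
               combined_score(scape, paste0(q[8], 8, b8)))
  double <- combined_score(scape, paste0(q[2], 2, b2, ":", q[5], 5, b5))
  triple <- combined_score(
    scape, paste0(q[2], 2, b2, ":", q[5], 5, b5, ":", q[8], 8, b8))
  expect_equal(double, sum(singles[1:2]))
  expect_equal(triple, sum(singles))
})

test_that("landscape files round-trip through the wide and long formats", {
  set.seed(406)
  aln <- random_alignment(8, 6, gap_prob = 0)
  scape <- single_landscape(aln)
  wide <- withr::local_tempfile(fileext = ".tsv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_landscape(scape, wide = wide, long = long)

  wdf <- utils::read.delim(wide, check.names = FALSE)
  expect_equal(nrow(wdf), 6L)
  expect_equal(as.matrix(wdf[, AA20]), unname(scape$scores),
               ignore_attr = TRUE)

  ldf <- utils::read.csv(long)
  expect_equal(nrow(ldf), 6L * 19L)
  probe <- ldf[ldf$mutant == paste0(scape$wildtype[2], 2, "W"), "score"]
  if (scape$wildtype[2] != "W")
    expect_equal(probe, unname(scape$scores[2, "W"]))
})
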