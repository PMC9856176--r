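# Consensus profiling, unique-residue scoring/calling, query sharing and
# span-length profiling.

test_that("consensus profiles follow the counting definition", {
  aln <- grouped_alignment(c("a1", "a2", "a3", "a4", "b1"),
                           c("g1", "g1", "g1", "g1", "solo"),
                           c("AAG-", "AAGC", "AAXC", "GA-C", "AC-T"))
  p <- build_consensus(aln, "g1")
  # col 1: A,A,A,G no gaps -> A at 75%
  expect_equal(p$consensus_residue[1], "A")
  expect_equal(p$consensus_score[1], 75)
  # col 3: G,G,X with one gap -> X counts in depth, never as consensus
  expect_equal(p$depth[3], 3L)
  expect_equal(p$consensus_residue[3], "G")
  expect_equal(p$consensus_score[3], 100 * 2 / 3)
  expect_equal(p$gap_fraction[3], 0.25)
  # single-sequence group: consensus equals the sequence at 100%
  solo <- build_consensus(aln, "solo")
  expect_equal(solo$consensus_residue, c("A", "C", NA, "T"))
  expect_equal(solo$consensus_score, c(100, 100, 0, 100))
  expect_error(build_consensus(aln, "nope"), "unknown or empty group")
})

test_that("modal ties break alphabetically and are flagged", {
  aln <- grouped_alignment(c("x1", "x2"), c("g", "g"), c("TA", "GA"))
  p <- build_consensus(aln, "g")
  expect_equal(p$consensus_residue[1], "G")  # G before T
  expect_true(p$tie[1])
  expect_false(p$tie[2])
})

test_that("profiles and unique scores match the brute-force oracle", {
  withr::with_seed(42, {
    for (i in 1:10) {
      aln <- random_alignment(sample(2:20, 1), sample(2:20, 1),
                              sample(20:80, 1))
      for (g in c("ga", "gb")) {
        p <- build_consensus(aln, g)
        o <- oracle_consensus(aln, g)
        expect_equal(p$consensus_residue, o$consensus)
        expect_equal(p$consensus_score, o$score)
        expect_equal(p$depth, o$depth)
      }
      sc <- unique_residue_scores(build_consensus(aln, "ga"),
                                  build_consensus(aln, "gb"))
      expect_equal(sc$unique_score, (sc$score_a + sc$score_b) / 2)
      # symmetry up to a/b labels
      sc_rev <- unique_residue_scores(build_consensus(aln, "gb"),
                                      build_consensus(aln, "ga"))
      expect_equal(sc_rev$unique_score, sc$unique_score)
    }
  })
})

test_that("unique-residue calls honour threshold, residues and chemistry", {
  mk_scores <- function(ra, rb, sa, sb) {
    data.frame(column = seq_along(ra), residue_a = ra, score_a = sa,
               gap_fraction_a = 0, residue_b = rb, score_b = sb,
               gap_fraction_b = 0, unique_score = (sa + sb) / 2,
               stringsAsFactors = FALSE)
  }
  sc <- mk_scores(c("D", "L", "A", "A"), c("K", "I", "A", "G"),
                  c(95, 95, 99, 80), c(89, 95, 99, 80))
  calls <- call_unique_residues(sc, 90)
  expect_equal(calls$column, c(1L, 2L))          # col 3 same residue, col 4 low
  expect_equal(calls$chemistry, c("different", "similar"))  # D/K vs L/I
  expect_equal(calls$unique_score[1], 92)
  # strict ">" by default; ">=" configurable
  sc90 <- mk_scores("D", "K", 90, 90)
  expect_equal(nrow(call_unique_residues(sc90, 90)), 0)
  expect_equal(nrow(call_unique_residues(sc90, 90, strict = FALSE)), 1)
  # column-count mismatch
  pa <- build_consensus(grouped_alignment("a", "g", "AC"), "g")
  pb <- build_consensus(grouped_alignment("b", "h", "ACD"), "h")
  expect_error(unique_residue_scores(pa, pb), "different numbers of columns")
})

test_that("majority-gap columns are excluded from calling", {
  sc <- data.frame(column = 1L, residue_a = "D", score_a = 100,
                   gap_fraction_a = 0.6, residue_b = "K", score_b = 100,
                   gap_fraction_b = 0, unique_score = 100)
  expect_equal(nrow(call_unique_residues(sc, 90)), 0)
  expect_equal(nrow(call_unique_residues(sc, 90, max_gap_fraction = NULL)), 1)
})

test_that("raising the threshold never adds a call", {
  withr::with_seed(7, {
    for (i in 1:10) {
      aln <- random_alignment(sample(3:15, 1), sample(3:15, 1),
                              sample(30:100, 1), gap_rate = 0.05)
      sc <- unique_residue_scores(build_consensus(aln, "ga"),
                                  build_consensus(aln, "gb"))
      c95 <- call_unique_residues(sc, 95)$column
      c90 <- call_unique_residues(sc, 90)$column
      c80 <- call_unique_residues(sc, 80)$column
      expect_true(all(c95 %in% c90))
      expect_true(all(c90 %in% c80))
    }
  })
})

test_that("query sharing counts matches against one side's consensus", {
  sim <- simulate_subfamily_alignment(
    alignment_sim_spec(10, 10, 50, n_different_chemistry = 6,
                       n_similar_chemistry = 4, gap_rate = 0, seed = 21))
  aln <- sim$alignment
  sc <- unique_residue_scores(build_consensus(aln, "group_a"),
                              build_consensus(aln, "group_b"))
  calls <- call_unique_residues(sc, 90)
  expect_equal(nrow(calls), 10)
  # a group-a member shares everything with side a
  member <- aln$records$sequence_id[aln$records$group_label == "group_a"][1]
  got <- shared_unique_residues(aln, member, calls, side = "a")
  expect_equal(got, list(n_shared = 10L, n_total = 10L))
  # a query agreeing with side a at exactly 5 planted columns scores 5/10
  q <- strsplit(aln$sequences[[member]], "")[[1]]
  flip <- calls$column[6:10]
  q[flip] <- calls$residue_b[6:10]
  aln2 <- grouped_alignment(c(aln$records$sequence_id, "query"),
                            c(aln$records$group_label, "query"),
                            c(unname(aln$sequences), paste(q, collapse = "")))
  expect_equal(shared_unique_residues(aln2, "query", calls, "a")$n_shared, 5L)
  expect_equal(shared_unique_residues(aln2, "query", calls, "b")$n_shared, 5L)
  # all-gap query shares nothing
  aln3 <- grouped_alignment(c(aln$records$sequence_id, "gapq"),
                            c(aln$records$group_label, "query"),
                            c(unname(aln$sequences),
                              paste(rep("-", aln$length), collapse = "")))
  expect_equal(shared_unique_residues(aln3, "gapq", calls, "a")$n_shared, 0L)
  expect_error(shared_unique_residues(aln, "missing", calls, "a"),
               "not in alignment")
})

test_that("span lengths count non-gap characters, per sequence and group", {
  aln <- grouped_alignment(c("a", "b"), c("long", "short"),
                           c("AC--G", "A----"))
  rl <- region_lengths(aln, 1, 5)
  expect_equal(rl$per_sequence$ungapped_length, c(3L, 1L))
  expect_error(region_lengths(aln, 3, 9), "span out of range")
  # planted loop-length contrast: long 14-26 vs short 3-6 in a 30-column span
  withr::with_seed(13, {
    span <- 30
    mk <- function(lens) vapply(lens, function(l) {
      pos <- sort(sample.int(span, l))
      x <- rep("-", span)
      x[pos] <- sample(AA_ALPHABET, l, replace = TRUE)
      paste(x, collapse = "")
    }, character(1))
    lens_a <- sample(14:26, 8, replace = TRUE)
    lens_b <- sample(3:6, 8, replace = TRUE)
    aln2 <- grouped_alignment(sprintf("s%02d", 1:16),
                              rep(c("long", "short"), each = 8),
                              c(mk(lens_a), mk(lens_b)))
    rl2 <- region_lengths(aln2, 1, span)
    bg <- rl2$by_group
    expect_equal(bg$min[bg$group_label == "long"], min(lens_a))
    expect_equal(bg$max[bg$group_label == "long"], max(lens_a))
    expect_equal(bg$min[bg$group_label == "short"], min(lens_b))
    expect_equal(bg$max[bg$group_label == "short"], max(lens_b))
    expect_true(bg$min[bg$group_label == "long"] >
                  bg$max[bg$group_label == "short"])
  })
})
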