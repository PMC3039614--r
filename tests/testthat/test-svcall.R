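test_that("discordant pairs with doubly-overlapping footprints form one cluster", {
  pairs <- rbind(
    make_pair_row("a", "chr1", 1000, 1400),
    make_pair_row("b", "chr1", 1010, 1390),
    make_pair_row("c", "chr1", 5000, 5400))  # far away
  cl <- cluster_discordant(pairs)
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(cl$n), c(1L, 2L))
  big <- cl[cl$n == 2L, ]
  expect_equal(big$left_fp_start, 1000L)
  expect_equal(big$left_fp_end, 1041L)
  expect_equal(big$predicted_start, big$left_fp_end)
  expect_equal(big$predicted_end, big$right_fp_start)
  expect_setequal(big$members[[1]], c("a", "b"))
})

test_that("left AND right footprints must both overlap to join a cluster", {
  pairs <- rbind(
    make_pair_row("a", "chr1", 1000, 1400),
    make_pair_row("b", "chr1", 1010, 1500))  # right mates 68 bp apart
  cl <- cluster_discordant(pairs)
  expect_equal(nrow(cl), 2L)
})

test_that("classes never merge and oversized pairs are discarded", {
  pairs <- rbind(
    make_pair_row("del", "chr1", 1000, 1400, category = "too_long"),
    make_pair_row("ins", "chr1", 1000, 1040, span = 72,
                  category = "too_short"),
    make_pair_row("huge", "chr1", 1000, 151000, category = "too_long"))
  cl <- cluster_discordant(pairs)
  expect_equal(sort(cl$sv_class), c("DEL", "INS"))
  expect_false(any(vapply(cl$members, function(m) "huge" %in% m,
                          logical(1))))
})

test_that("clustering is invariant under input permutation and conserves support", {
  set.seed(11)
  rows <- list()
  for (i in 1:40) {
    anchor <- sample.int(50000, 1)
    rows[[i]] <- make_pair_row(
      sprintf("p%02d", i), sample(c("chr1", "chr2"), 1), anchor,
      anchor + sample(250:500, 1),
      category = sample(c("too_long", "inverted_orientation"), 1))
  }
  pairs <- do.call(rbind, rows)
  cl1 <- cluster_discordant(pairs)
  for (rep in 1:3) {
    perm <- pairs[sample.int(nrow(pairs)), ]
    cl2 <- cluster_discordant(perm)
    expect_equal(cl2[, setdiff(names(cl2), "members")],
                 cl1[, setdiff(names(cl1), "members")])
    expect_equal(lapply(cl2$members, sort), lapply(cl1$members, sort))
  }
  # conservation: cluster sizes sum to surviving pair count per class
  for (cls in unique(cl1$sv_class)) {
    cat_name <- names(rrlsv:::SV_CLASSES)[rrlsv:::SV_CLASSES == cls]
    expect_equal(sum(cl1$n[cl1$sv_class == cls]),
                 sum(pairs$category == cat_name))
  }
})

test_that("the mapping-quality filter screens both sides and is monotone", {
  pairs <- rbind(make_pair_row("a", "chr1", 1000, 1400, mapq = 97),
                 make_pair_row("b", "chr1", 5000, 5400, mapq = 59),
                 make_pair_row("c", "chr1", 9000, 9400, mapq = 35))
  cl <- cluster_discordant(pairs)
  expect_equal(nrow(mapq_filter(cl, 60)), 1L)   # only the 97 cluster
  expect_equal(nrow(mapq_filter(cl, 35)), 3L)
  # one low side is enough to remove a cluster
  mixed <- make_pair_row("m", "chr1", 1000, 1400)
  mixed$mapq2 <- 59
  clm <- cluster_discordant(mixed)
  expect_equal(nrow(mapq_filter(clm, 60)), 0L)
  # monotonic: the stringent set is a subset of the relaxed one
  expect_true(all(mapq_filter(cl, 60)$cluster_id %in%
                    mapq_filter(cl, 35)$cluster_id))
})

test_that("the abundance rule scores deviation x support with a strict threshold", {
  mk <- function(cls, span, n) {
    data.frame(sv_class = cls, span = span, n = n)
  }
  # boundary: deviation 10 x 50 = 500 is NOT > 500
  r <- abundance_rule(mk("DEL", 230, 50))
  expect_equal(r$rule_score, 500)
  expect_equal(r$rule_outcome, "fail")
  r2 <- abundance_rule(mk("DEL", 230, 51))
  expect_equal(r2$rule_outcome, "pass")
  # insertions measure deviation downward from 100
  r3 <- abundance_rule(mk("INS", 86, 39))
  expect_equal(r3$rule_deviation, 14)
  expect_equal(r3$rule_score, 546)
  expect_equal(r3$rule_outcome, "pass")
  # beyond the calibrated deletion window the score is flagged
  r4 <- abundance_rule(mk("DEL", 868, 2))
  expect_equal(r4$rule_outcome, "pass")
  expect_false(r4$rule_in_window)
  expect_true(abundance_rule(mk("DEL", 700, 2))$rule_in_window)
  # inversions are outside the rule
  expect_equal(abundance_rule(mk("INV_BREAKPOINT", 300, 5))$rule_outcome,
               "not_applicable")
  # inconsistent clusters are errors
  expect_error(abundance_rule(mk("DEL", 220, 5)), "inconsistent")
  expect_error(abundance_rule(mk("INS", 100, 5)), "inconsistent")
  expect_error(abundance_rule(mk("INS", 20, 5)), "inconsistent")
})

test_that("rule passing is monotone in support and deviation", {
  set.seed(3)
  for (i in 1:50) {
    span <- sample(221:900, 1)
    n <- sample(1:200, 1)
    base <- abundance_rule(data.frame(sv_class = "DEL", span = span, n = n))
    more_n <- abundance_rule(data.frame(sv_class = "DEL", span = span,
                                        n = n + sample(1:50, 1)))
    more_dev <- abundance_rule(data.frame(sv_class = "DEL",
                                          span = span + sample(1:200, 1),
                                          n = n))
    if (base$rule_outcome == "pass") {
      expect_equal(more_n$rule_outcome, "pass")
      expect_equal(more_dev$rule_outcome, "pass")
    }
  }
})

test_that("deletion length follows the right-minus-left convention", {
  expect_equal(deletion_length(55356006, 55357163), 1157)
  expect_equal(deletion_length(43663736, 43663781), 45)
  expect_equal(deletion_length(10, 11), 1)
  expect_error(deletion_length(10, 10), "exceed")
  expect_error(deletion_length(10, 5), "exceed")
})

test_that("prioritisation requires mapq 60, flags features and ranks by aamq", {
  pairs <- rbind(make_pair_row("a", "chr1", 1000, 1400, mapq = 97),
                 make_pair_row("b", "chr1", 5000, 5400, mapq = 70),
                 make_pair_row("c", "chr1", 9000, 9400, mapq = 40))
  cl <- cluster_discordant(pairs)
  gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(900, 900), c(1600, 1500)))
  gm$type <- c("gene", "exon")
  gm$gene_id <- "g1"
  gm$transcript_id <- c(NA, "t1")
  ref <- c(chr1 = paste(rep("A", 12000), collapse = ""))
  ranked <- prioritize(cl, gm, ref)
  expect_equal(nrow(ranked), 2L)              # mapq 40 cluster dropped
  expect_equal(ranked$aamq[1], 97)            # exon-contained & highest aamq
  expect_true(ranked$in_feature[1])
  expect_false(ranked$in_feature[2])
  expect_true(all(ranked$clean_flanks))
  # no qualifying cluster: empty result
  expect_equal(nrow(prioritize(cl, gm, ref, mapq_threshold = 99.5)), 0L)
})
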