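test_that("genome simulation is seed-deterministic with controllable sites", {
  g1 <- simulate_genome(5000, seed = 3)
  g2 <- simulate_genome(5000, seed = 3)
  expect_identical(g1, g2)
  expect_false(identical(g1, simulate_genome(5000, seed = 4)))

  g0 <- simulate_genome(5000, site_rate = 0, seed = 3)
  expect_equal(gregexpr("AGCT", g0, fixed = TRUE)[[1L]][1L], -1L)

  gs <- simulate_genome(20000, site_rate = 1 / 200, seed = 3)
  n_sites <- length(gregexpr("AGCT", gs, fixed = TRUE)[[1L]])
  expect_gt(n_sites, 60)   # near the 100 requested
  expect_lt(n_sites, 140)
  expect_error(simulate_genome(0), "length")
  expect_error(simulate_genome(100, gc = 1.4), "gc")
})

test_that("SV implantation edits the haplotype and conserves length bookkeeping", {
  ref <- simulate_genome(50000, seed = 9)
  specs <- simulate_sv_specs(ref, n_del = 3, n_ins = 2, n_inv = 1,
                             min_gap = 500, seed = 10)
  imp <- implant_svs(ref, specs)
  d <- sum(specs$size[specs$sv_class == "DEL"])
  i <- sum(specs$size[specs$sv_class == "INS"])
  expect_equal(nchar(imp$haplotype), nchar(ref) - d + i)

  # single 500-bp deletion: the junction glues start to end+1
  one <- data.frame(sv_id = "d1", sv_class = "DEL", seq_id = "chr1",
                    start = 1000L, end = 1500L, size = 500L,
                    ins_seq = NA, stringsAsFactors = FALSE)
  h <- implant_svs(ref, one)
  expect_equal(nchar(h$haplotype), nchar(ref) - 500L)
  expect_equal(unname(substr(h$haplotype, 995, 1005)),
               paste0(substr(ref, 995, 1000), substr(ref, 1501, 1505)))

  # insertion grows the haplotype and sits after the breakpoint
  ins <- data.frame(sv_id = "i1", sv_class = "INS", seq_id = "chr1",
                    start = 2000L, end = 2000L, size = 60L,
                    ins_seq = strrep("T", 60), stringsAsFactors = FALSE)
  hi <- implant_svs(ref, ins)
  expect_equal(nchar(hi$haplotype), nchar(ref) + 60L)
  expect_equal(unname(substr(hi$haplotype, 2001, 2060)), strrep("T", 60))

  # inversion reverse-complements in place
  inv <- data.frame(sv_id = "v1", sv_class = "INV", seq_id = "chr1",
                    start = 3000L, end = 3099L, size = 100L,
                    ins_seq = NA, stringsAsFactors = FALSE)
  hv <- implant_svs(ref, inv)
  expect_equal(nchar(hv$haplotype), nchar(ref))
  expect_equal(unname(substr(hv$haplotype, 3000, 3099)),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(ref, 3000, 3099)))))

  # overlapping specs rejected
  two <- rbind(one, transform(one, sv_id = "d2", start = 1200L,
                              end = 1700L))
  expect_error(implant_svs(ref, two), "overlapping")
})

test_that("read simulation is deterministic and fragment-faithful", {
  st <- small_study()
  pm <- pool_model(pool_id = st$pool$pool_id, error_rate = 0,
                   q_low_rate = 0, leakage = 0, seed = 55)
  s1 <- simulate_pool_reads(st$reference, st$haplotype, st$truth, pm,
                            coverage = 2)
  s2 <- simulate_pool_reads(st$reference, st$haplotype, st$truth, pm,
                            coverage = 2)
  expect_identical(s1$reads1, s2$reads1)
  expect_identical(s1$manifest, s2$manifest)

  # every error-free read starts with the restriction tag CT (both mates)
  expect_true(all(startsWith(s1$reads1$seq, "CT")))
  expect_true(all(startsWith(s1$reads2$seq, "CT")))
  # mate 1 is the fragment prefix; mate 2 the reverse-complemented suffix
  mf <- s1$manifest[1, ]
  src <- if (mf$hap == "ref") st$reference else st$haplotype
  frag <- substr(src, mf$frag_start, mf$frag_start + mf$frag_len - 1L)
  expect_equal(s1$reads1$seq[1], unname(substr(frag, 1, 36)))
  expect_equal(s1$reads2$seq[1],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(
                   substr(frag, mf$frag_len - 35L, mf$frag_len)))))
  # with no leakage every sampled fragment is inside the size window
  expect_true(all(s1$manifest$frag_len >= 150 &
                    s1$manifest$frag_len <= 200))
})

test_that("allele frequency controls variant-fragment sampling", {
  st <- small_study()
  afcol <- paste0("af.", st$pool$pool_id)
  truth0 <- st$truth
  truth0[[afcol]] <- 0
  pm <- pool_model(pool_id = st$pool$pool_id, seed = 77)
  s0 <- simulate_pool_reads(st$reference, st$haplotype, truth0, pm,
                            coverage = 3)
  expect_true(all(s0$manifest$hap == "ref"))

  truth1 <- st$truth
  truth1[[afcol]] <- 1
  s1 <- simulate_pool_reads(st$reference, st$haplotype, truth1, pm,
                            coverage = 3)
  # SV-locus molecules all come from the variant haplotype
  expect_true(all(is.na(s1$manifest$sv_id) | s1$manifest$hap == "var"))
})

test_that("junction fragments project to reference span = fragment + deletion", {
  # constructed genome: deletion junction inside a selected fragment;
  # fillers are random motif-free sequence so 32-mers map uniquely
  filler <- function(k, seed) unname(simulate_genome(k, site_rate = 0,
                                                     seed = seed))
  # reference: fragment1 = 600 bp (will lose 420 -> 180), fragment2 = 170
  ref <- c(chr1 = paste0(strrep("T", 20),
                         "AGCT", filler(596, 101),
                         "AGCT", filler(166, 102),
                         "AGCT", strrep("T", 20)))
  # delete 420 bp from inside fragment 1 (fragment1 spans 23..622)
  del <- data.frame(sv_id = "d", sv_class = "DEL", seq_id = "chr1",
                    start = 120L, end = 540L, size = 420L, ins_seq = NA,
                    stringsAsFactors = FALSE)
  imp <- implant_svs(ref, del)
  vf <- select_size_range(digest(imp$haplotype), 150, 200)
  expect_equal(sort(vf$length), c(170L, 180L))
  mask <- detectability_mask(imp$truth, imp$haplotype, coverage = 10)
  expect_true(mask$detectable)
  expect_equal(mask$det_span, 180 + 420)  # fragment + deletion size
  expect_equal(mask$expected_support, 10)

  pm <- pool_model(error_rate = 0, q_low_rate = 0, leakage = 0, seed = 5)
  truth <- imp$truth
  truth$af.pool1 <- 1
  sim <- simulate_pool_reads(ref, imp$haplotype, truth, pm, coverage = 10)
  fp <- filter_pairs(sim$reads1, sim$reads2)
  a1 <- map_reads_unique(fp$pairs1$seq, ref)
  a2 <- map_reads_unique(fp$pairs2$seq, ref)
  pairs <- classify_pairs(pair_alignments(a1, a2))
  junction <- pairs[pairs$category == "too_long", ]
  expect_gt(nrow(junction), 0)
  expect_true(all(junction$outer_span == 600))  # 180 + 420
})

test_that("detectability requires a junction-spanning selected fragment", {
  filler <- function(k) paste(rep_len(c("A", "C"), k), collapse = "")
  # variant fragment of 1500 bp: junction fails size selection
  ref <- c(chr1 = paste0(strrep("T", 10), "AGCT", filler(1896), "AGCT",
                         strrep("T", 10)))
  del <- data.frame(sv_id = "d", sv_class = "DEL", seq_id = "chr1",
                    start = 500L, end = 900L, size = 400L, ins_seq = NA,
                    stringsAsFactors = FALSE)
  imp <- implant_svs(ref, del)
  expect_equal(digest(imp$haplotype)$length, 1500L)
  mask <- detectability_mask(imp$truth, imp$haplotype)
  expect_false(mask$detectable)

  # insertion: span = fragment - insertion; needs 32 bp mappable flanks
  ref2 <- c(chr1 = paste0(strrep("T", 10), "AGCT", filler(116), "AGCT",
                          strrep("T", 10)))
  # 120-bp reference fragment + 60-bp insertion -> 180-bp variant fragment,
  # reference span 120 >= 100: not discordant
  ins <- data.frame(sv_id = "i", sv_class = "INS", seq_id = "chr1",
                    start = 70L, end = 70L, size = 60L,
                    ins_seq = filler(60), stringsAsFactors = FALSE)
  m2 <- detectability_mask(implant_svs(ref2, ins)$truth,
                           implant_svs(ref2, ins)$haplotype)
  expect_false(m2$detectable)
  # 100-bp reference span from a 190-bp fragment with a 90-bp insertion
  # is still concordant (span must be < 100); 170-bp fragment works
  ref3 <- c(chr1 = paste0(strrep("T", 10), "AGCT", filler(76), "AGCT",
                          strrep("T", 10)))
  ins3 <- data.frame(sv_id = "i", sv_class = "INS", seq_id = "chr1",
                     start = 50L, end = 50L, size = 90L,
                     ins_seq = filler(90), stringsAsFactors = FALSE)
  imp3 <- implant_svs(ref3, ins3)
  expect_equal(digest(imp3$haplotype)$length, 170L)
  m3 <- detectability_mask(imp3$truth, imp3$haplotype)
  expect_true(m3$detectable)
  expect_equal(m3$det_span, 80)
})

test_that("haplotype sampling respects the gel model: leaked fragments are rare", {
  st <- small_study()
  pm <- pool_model(pool_id = st$pool$pool_id, leakage = 0.01,
                   leak_decay = 100, error_rate = 0, q_low_rate = 0,
                   seed = 41)
  sim <- simulate_pool_reads(st$reference, st$haplotype, st$truth, pm,
                             coverage = 5)
  out <- sim$manifest$frag_len < 150 | sim$manifest$frag_len > 200
  expect_lt(mean(out), 0.05)
  expect_gt(sum(out), 0)   # but leakage does happen at 1%
})

test_that("recovery evaluation matches calls to truth junctions", {
  truth <- data.frame(
    sv_id = c("d1", "i1"), sv_class = c("DEL", "INS"), seq_id = "chr1",
    start = c(1000L, 5000L), end = c(1400L, 5000L), size = c(400L, 70L),
    detectable = c(TRUE, TRUE), stringsAsFactors = FALSE)
  calls <- data.frame(
    sv_class = c("DEL", "DEL"), seq_id = "chr1",
    predicted_start = c(950L, 8000L), predicted_end = c(1450L, 8400L),
    left_fp_start = c(900L, 7950L), right_fp_end = c(1500L, 8450L),
    rule_outcome = c("pass", "pass"), stringsAsFactors = FALSE)
  ev <- evaluate_recovery(calls, truth)
  expect_equal(ev$n_detectable, 2L)
  expect_equal(ev$n_recovered, 1L)          # d1 found, i1 missed
  expect_equal(ev$recovery, 0.5)
  expect_equal(nrow(ev$false_positives), 1L)  # the call at 8000
})
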