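# Gene model fixture: one gene on chr1 [1000, 5000] with three exons.
fixture_models <- function(strand = "+") {
  gm <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1000, 1000, 2500, 4500), c(5000, 1200, 2700, 5000)),
    strand = strand)
  gm$type <- c("gene", "exon", "exon", "exon")
  gm$gene_id <- "g1"
  gm$transcript_id <- c(NA, "t1", "t1", "t1")
  gm
}

mk_locus <- function(seq_id, start, end, cls = "DEL") {
  data.frame(seq_id = seq_id, start = start, end = end, sv_class = cls,
             stringsAsFactors = FALSE)
}

test_that("location contexts are exclusive, exhaustive and correctly assigned", {
  gm <- fixture_models()
  loci <- rbind(mk_locus("chr1", 1500, 1600),   # intron
                mk_locus("chr1", 2600, 3000),   # overlaps exon 2
                mk_locus("chr1", 8000, 8100),   # outside the gene
                mk_locus("chr1", 4400, 4600))   # overlaps exon 3 edge
  ann <- classify_location(loci, gm)
  expect_equal(ann$context,
               c("intronic", "exonic", "intergenic", "exonic"))
  expect_equal(ann$gene_ids[1], "g1")
  expect_true(is.na(ann$gene_ids[3]))
  # unknown sequence: warning + intergenic
  expect_warning(out <- classify_location(mk_locus("chrZZ", 1, 10), gm),
                 "absent")
  expect_equal(out$context, "intergenic")
})

test_that("exon effects report loss, truncation and 5' deletion per strand", {
  gm <- fixture_models()
  ex <- gm[gm$type == "exon"]
  # removes the distal (3') end of the last exon
  expect_equal(exon_effect(list(seq_id = "chr1", start = 4800, end = 5600),
                           ex), "truncation last exon")
  # removes the 5' edge of exon 2
  expect_equal(exon_effect(list(seq_id = "chr1", start = 2400, end = 2600),
                           ex), "5' deletion exon 2")
  # whole exon 2 gone
  expect_equal(exon_effect(list(seq_id = "chr1", start = 2400, end = 2800),
                           ex), "loss exon 2")
  # intron only
  expect_equal(exon_effect(list(seq_id = "chr1", start = 1300, end = 2400),
                           ex), "none")
  # on the minus strand the genomic-left edge is the 3' edge
  exm <- fixture_models("-")
  exm <- exm[exm$type == "exon"]
  expect_equal(exon_effect(list(seq_id = "chr1", start = 2400,
                                end = 2600), exm),
               "truncation exon 2")
  # minus strand: genomic-last exon is exon 1; clipping its right edge
  # removes its 5' side
  expect_equal(exon_effect(list(seq_id = "chr1", start = 4800,
                                end = 5600), exm), "5' deletion exon 1")
})

test_that("repeat overlap reports de-duplicated classes or unannotated", {
  reps <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 150, 400), c(200, 260, 500)))
  reps$class <- c("CR1", "CR1", "trf")
  expect_equal(repeat_overlap(mk_locus("chr1", 180, 450), reps),
               c("CR1", "trf"))
  expect_equal(repeat_overlap(mk_locus("chr1", 190, 210), reps), "CR1")
  expect_equal(repeat_overlap(mk_locus("chr1", 700, 800), reps),
               "unannotated")
})

test_that("gene models load from GFF3 and BED12 through one interface", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t5000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1000\t5000\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1000\t1200\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\tsrc\texon\t2500\t2700\t.\t+\t.\tID=e2;Parent=t1"), gff)
  gm <- load_gene_models(gff)
  expect_setequal(as.character(gm$type), c("gene", "exon", "exon"))
  expect_equal(gm$transcript_id[gm$type == "exon"], c("t1", "t1"))

  bed <- withr::local_tempfile(fileext = ".bed")
  # BED12: one gene, two blocks (exons) at offsets 0 and 1500 of length 200
  writeLines(paste("chr1", 999, 5000, "g2", 0, "+", 999, 5000, "0",
                   2, "200,200,", "0,1500,", sep = "\t"), bed)
  gm2 <- load_gene_models(bed)
  expect_equal(sum(gm2$type == "exon"), 2L)
  ex <- gm2[gm2$type == "exon"]
  expect_equal(BiocGenerics::start(ex), c(1000L, 2500L))
  expect_equal(BiocGenerics::end(ex), c(1199L, 2699L))
})

test_that("breakpoints and sizes round-trip through product resolution", {
  set.seed(21)
  for (mh_len in c(0L, 2L, 5L)) {
    # reference = left flank + deleted segment + right flank, with the
    # first mh_len deleted bases equal to the first mh_len post-junction
    # bases (constructed microhomology)
    left <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
    delseg <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    if (mh_len > 0) {
      substr(delseg, 1, mh_len) <- substr(right, 1, mh_len)
    }
    # force a mismatch right after the homology on both sides
    br <- function(s, k) {
      substr(s, k + 1, k + 1) <- setdiff(c("A", "C", "G", "T"),
                                         c(substr(delseg, k + 1, k + 1),
                                           substr(s, k + 1, k + 1)))[1]
      s
    }
    right <- br(right, mh_len)
    # keep the junction from left-extending: last deleted base must differ
    # from the last left-flank base
    substr(delseg, 300, 300) <- setdiff(c("A", "C", "G", "T"),
                                        substr(left, 900, 900))[1]
    ref <- c(chr1 = paste0(left, delseg, right))
    product <- paste0(left, right)          # variant allele
    res <- resolve_breakpoints(product, ref, "chr1", 1, nchar(ref))
    expect_equal(res$status, "resolved")
    expect_equal(res$left_breakpoint, 900L)  # left-aligned
    expect_equal(res$right_breakpoint, 1200L)
    expect_equal(res$size, 300L)
    expect_equal(nchar(res$microhomology), mh_len)
    expect_equal(res$microhomology,
                 detect_microhomology(ref, "chr1", 900, 1200))
  }
})

test_that("a product identical to the reference yields no junction", {
  ref <- c(chr1 = unname(simulate_genome(1500, seed = 77)))
  res <- resolve_breakpoints(substr(ref, 101, 900), ref, "chr1", 1, 1500)
  expect_equal(res$status, "failed")
  expect_match(res$reason, "no deletion junction")
})

test_that("microhomology detection returns the longest shared junction prefix", {
  #              123456789012345
  ref <- c(c1 = "AAAGTCCCGTAAATT")
  # deletion (3,8) removes GTCCC; both the deleted segment and the
  # post-junction sequence start GT, third bases differ
  expect_equal(detect_microhomology(ref, "c1", 3, 8), "GT")
  # no shared prefix
  expect_equal(detect_microhomology(ref, "c1", 1, 4), "")
  expect_error(detect_microhomology(ref, "c1", 0, 5), "bounds")
  expect_error(detect_microhomology(ref, "c1", 7, 7), "bounds")
})

test_that("random junctions rarely show homology and constructed copies show k", {
  # deleted segment equal to the following k bases -> microhomology k
  ref <- c(c1 = paste0(strrep("A", 10), "GATTACA", "GATTACA",
                       strrep("C", 10)))
  expect_equal(detect_microhomology(ref, "c1", 10, 17), "GATTACA")
})
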