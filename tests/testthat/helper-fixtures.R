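# Shared fixtures and independent oracles, built in code.

# Naive regex oracle for restriction digestion: scan for the motif, apply
# the cut offset, return internal fragments. Independent of digest().
oracle_digest <- function(seq, motif = "AGCT", cut_offset = 2L) {
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
  hits <- hits[hits != -1L]
  cuts <- hits + cut_offset - 1L
  cuts <- cuts[cuts >= 1L & cuts < nchar(seq)]
  if (length(cuts) < 2L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = cuts[-length(cuts)] + 1L, end = cuts[-1L])
}

# A genome whose internal AluI fragments have exactly the given lengths
# (>= 4 bp each). Fillers use only A/C so no accidental AGCT can arise.
make_fragment_genome <- function(frag_lens, seq_id = "chr1") {
  stopifnot(all(frag_lens >= 4L))
  fillers <- vapply(frag_lens - 4L, function(k) {
    paste(rep_len(c("A", "C"), k), collapse = "")
  }, character(1))
  s <- paste0("TTT", paste0("AGCT", fillers, collapse = ""), "AGCTTTT")
  stats::setNames(s, seq_id)
}

# One read record
read_rec <- function(seq, qual = NULL, id = "r1") {
  if (is.null(qual)) qual <- strrep("F", nchar(seq))  # phred 37
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

qchar <- function(q) rawToChar(as.raw(33L + q))

# Hand-built mapped-pair rows for clustering tests (already classified).
make_pair_row <- function(pair_id, seq_id, s1, s2, span = NULL,
                          category = "too_long", strand1 = "+",
                          strand2 = "-", mapq = 99, read_len = 32L) {
  e1 <- s1 + read_len - 1L
  e2 <- s2 + read_len - 1L
  if (is.null(span)) span <- max(e1, e2) - min(s1, s2) + 1L
  data.frame(pair_id = pair_id, status1 = "mapped", seq_id1 = seq_id,
             start1 = s1, end1 = e1, strand1 = strand1, mismatches1 = 0L,
             mapq1 = mapq, status2 = "mapped", seq_id2 = seq_id,
             start2 = s2, end2 = e2, strand2 = strand2, mismatches2 = 0L,
             mapq2 = mapq, outer_span = span,
             category = factor(category, levels = rrlsv:::PAIR_CATEGORIES),
             stringsAsFactors = FALSE)
}

# A small deterministic study shared by several test files (cached).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(seed = 7, genome_bp = 4e5, n_del = 10L,
                               n_ins = 4L, n_inv = 2L)
    }
    cache
  }
})

# Run qc + mapping + classification on a study's reads.
study_pairs <- function(st) {
  fp <- filter_pairs(st$sim$reads1, st$sim$reads2)
  a1 <- map_reads_unique(fp$pairs1$seq, st$reference)
  a2 <- map_reads_unique(fp$pairs2$seq, st$reference)
  classify_pairs(pair_alignments(a1, a2,
                                 pair_id = sub("/1$", "", fp$pairs1$id)))
}
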