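# Unique best-hit read mapping (toy mapper), SAM ingestion, and insert-size
# based classification of read pairs.
#
# The toy mapper exists so the test bed never needs an external aligner: it
# reports a location only when exactly one locus attains the best score and
# that score is at most one mismatch, mirroring the unique-<=1-mismatch
# constraint of the analysis. Real alignments are ingested from name-grouped
# SAM instead.

SEED_LEN <- 16L

#' Map reads to a reference, unique best hit with at most one mismatch
#'
#' Exact matches are found on both strands with a constant-width dictionary
#' scan; reads without an exact hit are rescued by a half-read seed search
#' (a one-mismatch alignment always contains one exact half). A read is
#' `mapped` only when exactly one locus attains the best mismatch count
#' (0 or 1); several co-optimal loci give `ambiguous`, none give `unmapped`.
#'
#' Mapping qualities are a deterministic package convention: `mapq_exact`
#' (default 99) for a unique exact hit and `mapq_onemm` (default 80) for a
#' unique one-mismatch hit; ambiguous and unmapped reads carry NA.
#'
#' @param reads Character vector of read sequences (constant width).
#' @param reference Genome as accepted by [digest()].
#' @param mapq_exact,mapq_onemm Mapping qualities assigned to unique exact /
#'   unique one-mismatch hits.
#' @return data.frame with one row per input read: `status`
#'   (`mapped`/`ambiguous`/`unmapped`), `seq_id`, `start` (1-based),
#'   `strand`, `mismatches`, `mapq`.
#' @export
map_reads_unique <- function(reads, reference, mapq_exact = 99L,
                             mapq_onemm = 80L) {
  ref <- as_dna_set(reference)
  n <- length(reads)
  empty <- data.frame(status = character(0), seq_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), mapq = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  w <- unique(nchar(reads))
  if (length(w) != 1L) stop("reads must have constant width", call. = FALSE)
  if (w < SEED_LEN) {
    stop("read shorter than seed length (", SEED_LEN, " bp)", call. = FALSE)
  }
  u <- unique(reads)
  uset <- Biostrings::DNAStringSet(u)
  urc <- Biostrings::reverseComplement(uset)

  collect_hits <- function(pd, strand) {
    hits <- vector("list", length(ref))
    for (ci in seq_along(ref)) {
      m <- Biostrings::matchPDict(pd, ref[[ci]])
      st <- Biostrings::startIndex(m)
      len <- lengths(st)
      if (sum(len) == 0L) next
      hits[[ci]] <- data.frame(
        pattern = rep.int(seq_along(st), len),
        seq_id = names(ref)[ci],
        start = unlist(st, use.names = FALSE),
        strand = strand, stringsAsFactors = FALSE)
    }
    do.call(rbind, hits)
  }
  hf <- collect_hits(Biostrings::PDict(uset), "+")
  hr <- collect_hits(Biostrings::PDict(urc), "-")
  exact <- rbind(hf, hr)
  n_exact <- integer(length(u))
  if (!is.null(exact) && nrow(exact)) {
    tab <- table(factor(exact$pattern, levels = seq_along(u)))
    n_exact <- as.integer(tab)
  }

  res_u <- data.frame(status = rep("unmapped", length(u)),
                      seq_id = NA_character_, start = NA_integer_,
                      strand = NA_character_, mismatches = NA_integer_,
                      mapq = NA_integer_, stringsAsFactors = FALSE)
  uniq1 <- which(n_exact == 1L)
  if (length(uniq1) && !is.null(exact)) {
    one <- exact[exact$pattern %in% uniq1, , drop = FALSE]
    res_u$status[one$pattern] <- "mapped"
    res_u$seq_id[one$pattern] <- one$seq_id
    res_u$start[one$pattern] <- one$start
    res_u$strand[one$pattern] <- one$strand
    res_u$mismatches[one$pattern] <- 0L
    res_u$mapq[one$pattern] <- as.integer(mapq_exact)
  }
  res_u$status[n_exact >= 2L] <- "ambiguous"

  rescue <- which(n_exact == 0L)
  if (length(rescue)) {
    res_u[rescue, ] <- rescue_one_mismatch(u[rescue], uset[rescue],
                                           urc[rescue], ref, w,
                                           as.integer(mapq_onemm))
  }
  res_u[match(reads, u), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# One-mismatch rescue via exact half-read seeds. For each read (both
# orientations) the two 16-bp halves are scanned exactly; every seed hit
# proposes a read placement which is verified by edit distance. Unique
# one-mismatch placements are reported; >=2 co-optimal placements are
# ambiguous.
rescue_one_mismatch <- function(useq, uset, urc, ref, w, mapq_onemm) {
  k <- length(useq)
  # seed order: (read1 fwd L, read1 fwd R, read1 rev L, read1 rev R, read2...)
  seeds <- vector("list", 4L * k)
  for (i in seq_len(k)) {
    f <- uset[[i]]; r <- urc[[i]]
    seeds[[4L * i - 3L]] <- Biostrings::subseq(f, 1L, SEED_LEN)
    seeds[[4L * i - 2L]] <- Biostrings::subseq(f, w - SEED_LEN + 1L, w)
    seeds[[4L * i - 1L]] <- Biostrings::subseq(r, 1L, SEED_LEN)
    seeds[[4L * i]] <- Biostrings::subseq(r, w - SEED_LEN + 1L, w)
  }
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  cand <- vector("list", length(ref))
  for (ci in seq_along(ref)) {
    m <- Biostrings::matchPDict(pd, ref[[ci]])
    st <- Biostrings::startIndex(m)
    len <- lengths(st)
    if (sum(len) == 0L) next
    sid <- rep.int(seq_along(st), len)
    pos <- unlist(st, use.names = FALSE)
    read_i <- (sid - 1L) %/% 4L + 1L
    half <- (sid - 1L) %% 4L       # 0 fwdL, 1 fwdR, 2 revL, 3 revR
    start <- ifelse(half %% 2L == 0L, pos, pos - (w - SEED_LEN))
    cand[[ci]] <- data.frame(read_i = read_i, chr_i = ci,
                             orient = ifelse(half < 2L, "+", "-"),
                             start = start, stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  res <- data.frame(status = rep("unmapped", k), seq_id = NA_character_,
                    start = NA_integer_, strand = NA_character_,
                    mismatches = NA_integer_, mapq = NA_integer_,
                    stringsAsFactors = FALSE)
  if (is.null(cand) || nrow(cand) == 0L) return(res)
  cand <- cand[cand$start >= 1L, , drop = FALSE]
  chrlen <- BiocGenerics::width(ref)
  cand <- cand[cand$start + w - 1L <= chrlen[cand$chr_i], , drop = FALSE]
  cand <- unique(cand)
  if (nrow(cand) == 0L) return(res)
  split_idx <- split(seq_len(nrow(cand)),
                     paste(cand$read_i, cand$chr_i, cand$orient))
  valid <- vector("list", length(split_idx))
  vi <- 0L
  for (rows in split_idx) {
    ri <- cand$read_i[rows[1L]]
    ci <- cand$chr_i[rows[1L]]
    orient <- cand$orient[rows[1L]]
    pat <- if (orient == "+") uset[[ri]] else urc[[ri]]
    ned <- Biostrings::neditStartingAt(pat, ref[[ci]],
                                       starting.at = cand$start[rows])
    ok <- which(ned <= 1L)
    if (length(ok)) {
      vi <- vi + 1L
      valid[[vi]] <- data.frame(read_i = ri, chr_i = ci, orient = orient,
                                start = cand$start[rows][ok],
                                stringsAsFactors = FALSE)
    }
  }
  if (vi == 0L) return(res)
  valid <- do.call(rbind, valid[seq_len(vi)])
  counts <- table(factor(valid$read_i, levels = seq_len(k)))
  for (i in which(as.integer(counts) == 1L)) {
    v <- valid[valid$read_i == i, , drop = FALSE]
    res$status[i] <- "mapped"
    res$seq_id[i] <- names(ref)[v$chr_i]
    res$start[i] <- v$start
    res$strand[i] <- v$orient
    res$mismatches[i] <- 1L
    res$mapq[i] <- mapq_onemm
  }
  res$status[as.integer(counts) >= 2L] <- "ambiguous"
  res
}

#' Combine two mate alignment tables into a pair table
#'
#' @param aln1,aln2 Alignment tables from [map_reads_unique()] (or SAM
#'   ingestion), one row per mate, synchronised by position.
#' @param pair_id Pair identifiers (defaults to row numbers).
#' @param read_length Read length in bp used to compute alignment ends.
#' @return A mapped-pair data.frame (one row per pair) with per-mate fields
#'   suffixed `1`/`2`.
#' @export
pair_alignments <- function(aln1, aln2, pair_id = NULL, read_length = 32L) {
  stopifnot(nrow(aln1) == nrow(aln2))
  if (is.null(pair_id)) pair_id <- sprintf("pair%06d", seq_len(nrow(aln1)))
  data.frame(
    pair_id = pair_id,
    status1 = aln1$status, seq_id1 = aln1$seq_id, start1 = aln1$start,
    end1 = aln1$start + read_length - 1L, strand1 = aln1$strand,
    mismatches1 = aln1$mismatches, mapq1 = aln1$mapq,
    status2 = aln2$status, seq_id2 = aln2$seq_id, start2 = aln2$start,
    end2 = aln2$start + read_length - 1L, strand2 = aln2$strand,
    mismatches2 = aln2$mismatches, mapq2 = aln2$mapq,
    stringsAsFactors = FALSE
  )
}

PAIR_CATEGORIES <- c("concordant", "too_short", "too_long",
                     "inverted_orientation", "diff_chrom", "one_end",
                     "neither_end")

#' Classify read pairs by mapping state, orientation and outer span
#'
#' The outer span is the distance from the leftmost mapped base of one mate
#' to the rightmost mapped base of the other (inclusive), so a concordantly
#' sequenced fragment's span equals its length. Pairs are `concordant` when
#' both mates map to one sequence in convergent (forward/reverse)
#' orientation with `span_min <= span <= span_max`; same-sequence convergent
#' pairs outside that window are `too_long` (deletion signal) or `too_short`
#' (insertion signal); non-convergent same-sequence pairs are
#' `inverted_orientation`; the remaining categories are `diff_chrom`,
#' `one_end` and `neither_end`. Categories partition all pairs and are
#' invariant to mate order.
#'
#' @param pairs Pair table from [pair_alignments()] or [read_sam_pairs()].
#' @param span_min,span_max Concordance window in bp (defaults 100 / 220).
#' @return `pairs` with added `outer_span` (NA unless both mates map to one
#'   sequence) and `category` columns.
#' @export
classify_pairs <- function(pairs, span_min = 100L, span_max = 220L) {
  m1 <- pairs$status1 == "mapped"
  m2 <- pairs$status2 == "mapped"
  same <- m1 & m2 & pairs$seq_id1 == pairs$seq_id2
  span <- rep(NA_integer_, nrow(pairs))
  span[same] <- pmax(pairs$end1[same], pairs$end2[same]) -
    pmin(pairs$start1[same], pairs$start2[same]) + 1L
  # leftmost mate (ties: treat opposite strands as convergent)
  left_strand <- ifelse(pairs$start1 <= pairs$start2,
                        pairs$strand1, pairs$strand2)
  right_strand <- ifelse(pairs$start1 <= pairs$start2,
                         pairs$strand2, pairs$strand1)
  convergent <- same & left_strand == "+" & right_strand == "-"

  category <- rep("neither_end", nrow(pairs))
  category[xor(m1, m2)] <- "one_end"
  category[m1 & m2 & pairs$seq_id1 != pairs$seq_id2] <- "diff_chrom"
  category[same & !convergent] <- "inverted_orientation"
  category[convergent & span < span_min] <- "too_short"
  category[convergent & span > span_max] <- "too_long"
  category[convergent & span >= span_min & span <= span_max] <- "concordant"
  pairs$outer_span <- span
  pairs$category <- factor(category, levels = PAIR_CATEGORIES)
  pairs
}

#' Insert-size histogram over same-sequence convergent pairs
#'
#' Includes discordant spans (too short / too long), so the histogram is the
#' diagnostic for choosing concordance thresholds.
#'
#' @param pairs Classified pair table.
#' @return data.frame (`span`, `count`) of class `insert_histogram`.
#' @export
insert_size_histogram <- function(pairs) {
  keep <- pairs$category %in% c("concordant", "too_short", "too_long")
  tab <- table(pairs$outer_span[keep])
  h <- data.frame(span = as.integer(names(tab)),
                  count = as.integer(tab))
  class(h) <- c("insert_histogram", "data.frame")
  h
}

#' Modal insert size
#'
#' The most frequent outer span within the concordance window; used as the
#' baseline for call size estimates.
#'
#' @param hist An `insert_histogram`.
#' @param span_min,span_max Concordance window.
#' @return Integer span, or NA if no pair lies in the window.
#' @export
modal_insert <- function(hist, span_min = 100L, span_max = 220L) {
  h <- hist[hist$span >= span_min & hist$span <= span_max, , drop = FALSE]
  if (nrow(h) == 0L) return(NA_integer_)
  h$span[which.max(h$count)]
}

#' Per-category pair accounting
#'
#' @param pairs Classified pair table.
#' @return data.frame with `category`, `count`, `percent`.
#' @export
category_summary <- function(pairs) {
  tab <- table(pairs$category)
  data.frame(category = names(tab), count = as.integer(tab),
             percent = if (nrow(pairs)) 100 * as.integer(tab) / nrow(pairs)
             else rep(0, length(tab)),
             stringsAsFactors = FALSE)
}

#' Read name-grouped paired alignments from SAM
#'
#' Primary alignments only; the pair's outer span is recomputed from the
#' mate positions (TLEN is ignored). Mapping quality and the NM tag are
#' preserved as reported by the aligner.
#'
#' @param path SAM file with header.
#' @param read_length Read length fallback when sequences are absent.
#' @return Mapped-pair data.frame as from [pair_alignments()].
#' @export
read_sam_pairs <- function(path, read_length = 32L) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq", "qwidth"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  d <- data.frame(qname = x$qname, flag = x$flag,
                  seq_id = as.character(x$rname), start = x$pos,
                  strand = as.character(x$strand), mapq = x$mapq,
                  qwidth = x$qwidth, nm = x$tag$NM,
                  stringsAsFactors = FALSE)
  d <- d[bitwAnd(d$flag, 0x900L) == 0L, , drop = FALSE]  # primary only
  d$mate <- ifelse(bitwAnd(d$flag, 0x40L) > 0L, 1L,
                   ifelse(bitwAnd(d$flag, 0x80L) > 0L, 2L, NA_integer_))
  d$mapped <- bitwAnd(d$flag, 0x4L) == 0L
  if (anyNA(d$mate)) stop("SAM records lack first/last-segment flags",
                          call. = FALSE)
  first <- d[d$mate == 1L, , drop = FALSE]
  second <- d[d$mate == 2L, , drop = FALSE]
  idx <- match(first$qname, second$qname)
  if (anyNA(idx)) {
    stop("unpaired SAM record: ", first$qname[which(is.na(idx))[1L]],
         call. = FALSE)
  }
  second <- second[idx, , drop = FALSE]
  as_aln <- function(m) {
    data.frame(
      status = ifelse(m$mapped, "mapped", "unmapped"),
      seq_id = ifelse(m$mapped, m$seq_id, NA_character_),
      start = ifelse(m$mapped, m$start, NA_integer_),
      strand = ifelse(m$mapped, m$strand, NA_character_),
      mismatches = if (!is.null(m$nm)) m$nm else NA_integer_,
      mapq = m$mapq, stringsAsFactors = FALSE)
  }
  rl <- stats::median(d$qwidth[d$mapped], na.rm = TRUE)
  if (is.na(rl)) rl <- read_length
  pair_alignments(as_aln(first), as_aln(second), pair_id = first$qname,
                  read_length = as.integer(rl))
}
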