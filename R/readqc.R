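# Read qualification: restriction-tag check, fixed-length trimming, and a
# per-base phred floor. Reads are handled as plain data.frames with columns
# id / seq / qual (Sanger phred+33 encoding by default); FASTQ conversion
# happens at the boundary via Biostrings.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (gzip accepted).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read table as FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path Output file; ".gz" suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

# Decode a phred string; errors on characters below the encoding offset.
phred_values <- function(qual, offset = 33L) {
  v <- utf8ToInt(qual) - offset
  if (any(v < 0L)) {
    stop("malformed quality string (character below encoding offset): ",
         qual, call. = FALSE)
  }
  v
}

#' Qualify reads against tag, length and quality requirements
#'
#' A read qualifies when it is at least `trim_to` bases long, starts with the
#' restriction tag (the post-cut half-site, "CT" for AluI), and every base of
#' the trimmed read has phred quality >= `min_q`. Qualified reads are
#' returned trimmed to exactly `trim_to` bases. Rejections are classified as
#' `too_short`, `no_tag` or `low_quality` (checked in that order).
#'
#' @param reads Read table (`id`, `seq`, `qual`) or a single read as a
#'   list with `seq` and `qual`.
#' @param tag Required leading sequence (default "CT").
#' @param trim_to Trimmed read length in bp (default 32).
#' @param min_q Minimum per-base phred score (default 20).
#' @param qual_offset Phred encoding offset (default 33, Sanger).
#' @return The read table with added `status` column
#'   (`ok`/`too_short`/`no_tag`/`low_quality`); `seq` and `qual` of
#'   qualified reads are trimmed to `trim_to` bases.
#' @export
qualify_reads <- function(reads, tag = "CT", trim_to = 32L, min_q = 20L,
                          qual_offset = 33L) {
  if (!is.data.frame(reads)) {
    reads <- data.frame(id = "read", seq = reads$seq, qual = reads$qual,
                        stringsAsFactors = FALSE)
  }
  n <- nrow(reads)
  if (n == 0L) {
    reads$status <- character(0)
    return(reads)
  }
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    bad <- which(nchar(reads$seq) != nchar(reads$qual))[1L]
    stop("malformed record (sequence/quality length mismatch) at read ",
         reads$id[bad], call. = FALSE)
  }
  trim_to <- as.integer(trim_to)
  status <- rep("ok", n)
  status[nchar(reads$seq) < trim_to] <- "too_short"
  has_tag <- startsWith(reads$seq, tag)
  status[status == "ok" & !has_tag] <- "no_tag"

  cand <- which(status == "ok")
  if (length(cand)) {
    qt <- substr(reads$qual[cand], 1L, trim_to)
    if (any(grepl(sprintf("[\\x01-\\x%02X]", qual_offset - 1L), qt,
                  perl = TRUE))) {
      stop("malformed quality string (character below encoding offset)",
           call. = FALSE)
    }
    # a base fails iff its code is below offset + min_q
    low <- grepl(sprintf("[\\x%02X-\\x%02X]", qual_offset,
                         qual_offset + as.integer(min_q) - 1L),
                 qt, perl = TRUE)
    status[cand[low]] <- "low_quality"
  }
  ok <- status == "ok"
  reads$seq[ok] <- substr(reads$seq[ok], 1L, trim_to)
  reads$qual[ok] <- substr(reads$qual[ok], 1L, trim_to)
  reads$status <- status
  reads
}

#' Qualify read pairs and account for every rejection
#'
#' Applies [qualify_reads()] to both mates of synchronised read streams; a
#' pair is emitted only when BOTH mates qualify. Counts partition the input
#' exactly: `raw_pairs = qualified_pairs + too_short_failures + tag_failures
#' + quality_failures`. When the two mates fail for different reasons the
#' pair is attributed to the higher-precedence reason
#' (too_short > no_tag > low_quality).
#'
#' @param reads1,reads2 Mate read tables (`id`, `seq`, `qual`) or FASTQ
#'   paths, synchronised by record order and read id.
#' @param tag,trim_to,min_q,qual_offset See [qualify_reads()].
#' @return A list with `pairs1`, `pairs2` (qualified, trimmed read tables)
#'   and `report` (class `qc_report`).
#' @export
filter_pairs <- function(reads1, reads2, tag = "CT", trim_to = 32L,
                         min_q = 20L, qual_offset = 33L) {
  if (is.character(reads1)) reads1 <- read_fastq(reads1)
  if (is.character(reads2)) reads2 <- read_fastq(reads2)
  if (nrow(reads1) != nrow(reads2)) {
    stop("desynchronized mate streams: ", nrow(reads1), " vs ",
         nrow(reads2), " records", call. = FALSE)
  }
  base_id <- function(x) sub("[/ _][12]$", "", sub(" .*$", "", x))
  if (nrow(reads1) > 0L) {
    mism <- base_id(reads1$id) != base_id(reads2$id)
    if (any(mism)) {
      i <- which(mism)[1L]
      stop("desynchronized mate streams at record ", i, ": '",
           reads1$id[i], "' vs '", reads2$id[i], "'", call. = FALSE)
    }
  }
  q1 <- qualify_reads(reads1, tag, trim_to, min_q, qual_offset)
  q2 <- qualify_reads(reads2, tag, trim_to, min_q, qual_offset)
  rank <- c(ok = 0L, low_quality = 1L, no_tag = 2L, too_short = 3L)
  worst <- pmax(rank[q1$status], rank[q2$status])
  report <- structure(list(
    raw_pairs = nrow(reads1),
    too_short_failures = sum(worst == 3L),
    tag_failures = sum(worst == 2L),
    quality_failures = sum(worst == 1L),
    qualified_pairs = sum(worst == 0L)
  ), class = "qc_report")
  keep <- worst == 0L
  drop_status <- function(d) d[, setdiff(names(d), "status"), drop = FALSE]
  list(pairs1 = drop_status(q1[keep, , drop = FALSE]),
       pairs2 = drop_status(q2[keep, , drop = FALSE]),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d raw pairs: %d qualified, %d tag, %d quality, %d short\n",
    x$raw_pairs, x$qualified_pairs, x$tag_failures, x$quality_failures,
    x$too_short_failures))
  invisible(x)
}

#' Write a QC report as TSV or JSON
#'
#' @param report A `qc_report`.
#' @param path Output file; format chosen by extension (".json" vs TSV).
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  } else {
    utils::write.table(as.data.frame(unclass(report)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
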