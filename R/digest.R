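# In-silico restriction digestion and RRL size selection.
#
# Internal coordinates are 1-based inclusive throughout the package; BED
# output converts to 0-based half-open at the boundary only.

#' Restriction enzyme specification
#'
#' Describes a blunt-cutting restriction enzyme by its recognition motif and
#' the cut position within the motif. The default is AluI, which recognises
#' AGCT and cuts bluntly between the G and the C (`cut_offset = 2`), so every
#' internal fragment starts with "CT" and ends with "AG".
#'
#' @param motif Recognition motif, A/C/G/T only.
#' @param cut_offset Number of bases from the motif start to the cut
#'   (0 to `nchar(motif)`); the cut falls after `motif[cut_offset]`.
#' @return An object of class `restriction_spec`.
#' @examples
#' restriction_spec()          # AluI
#' restriction_spec("GATC", 0) # a 5' overhang cutter
#' @export
restriction_spec <- function(motif = "AGCT", cut_offset = 2L) {
  motif <- toupper(as.character(motif))
  if (length(motif) != 1L || !nzchar(motif) ||
      grepl("[^ACGT]", motif)) {
    stop("motif must be a non-empty string over A/C/G/T", call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(motif)) {
    stop("cut_offset must lie in [0, nchar(motif)]", call. = FALSE)
  }
  structure(list(motif = motif, cut_offset = cut_offset),
            class = "restriction_spec")
}

#' @export
print.restriction_spec <- function(x, ...) {
  cat(sprintf("<restriction_spec> motif %s, cut after base %d (%s^%s)\n",
              x$motif, x$cut_offset,
              substr(x$motif, 1L, x$cut_offset),
              substr(x$motif, x$cut_offset + 1L, nchar(x$motif))))
  invisible(x)
}

as_dna_set <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    if (length(genome) == 0L) return(Biostrings::DNAStringSet())
    if (is.null(names(genome))) {
      names(genome) <- if (length(genome) == 1L) "seq1" else
        paste0("seq", seq_along(genome))
    }
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a DNAStringSet, a named character vector, ",
       "or a FASTA path", call. = FALSE)
}

#' In-silico digestion of a genome
#'
#' Scans each sequence for exact occurrences of the recognition motif
#' (ambiguity codes and N never match) and cuts at every site. Only internal
#' fragments -- those flanked by a cut on both sides -- represent excisable
#' restriction fragments and are returned by default; the terminal pieces of
#' each sequence (one sheared end) can be included for inspection and are
#' marked by the `terminal` column.
#'
#' @param genome A `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or a FASTA file path.
#' @param spec A [restriction_spec()].
#' @param include_terminal Also return chromosome-end pieces (default FALSE).
#' @return A data.frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive), `length`, and `terminal`.
#' @examples
#' digest(c(chr = "TTAGCTTTTAGCTAA"))  # one internal fragment, "CTTTTAG"
#' @export
digest <- function(genome, spec = restriction_spec(),
                   include_terminal = FALSE) {
  stopifnot(inherits(spec, "restriction_spec"))
  dna <- as_dna_set(genome)
  out <- vector("list", length(dna))
  for (i in seq_along(dna)) {
    s <- dna[[i]]
    hits <- Biostrings::matchPattern(spec$motif, s, fixed = TRUE)
    m <- BiocGenerics::start(hits)
    if (length(m) == 0L) {
      out[[i]] <- NULL
      next
    }
    # cut falls after reference position m + cut_offset - 1
    cuts <- m + spec$cut_offset - 1L
    cuts <- cuts[cuts >= 1L & cuts < length(s)]
    if (length(cuts) == 0L) {
      out[[i]] <- NULL
      next
    }
    starts <- cuts[-length(cuts)] + 1L
    ends <- cuts[-1L]
    terminal <- logical(length(starts))
    if (include_terminal) {
      starts <- c(1L, starts, cuts[length(cuts)] + 1L)
      ends <- c(cuts[1L], ends, length(s))
      terminal <- c(TRUE, terminal, TRUE)
    }
    keep <- ends >= starts
    out[[i]] <- data.frame(
      seq_id = names(dna)[i],
      start = starts[keep], end = ends[keep],
      terminal = terminal[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), terminal = logical(),
                      stringsAsFactors = FALSE)
  }
  res$length <- res$end - res$start + 1L
  rownames(res) <- NULL
  res[, c("seq_id", "start", "end", "length", "terminal")]
}

#' Size-select restriction fragments
#'
#' Keeps fragments whose length lies in `[min_bp, max_bp]` (inclusive),
#' emulating gel excision of the RRL size window.
#'
#' @param fragments Fragment table from [digest()].
#' @param min_bp,max_bp Inclusive length bounds in bp.
#' @return The filtered fragment table, original order preserved.
#' @export
select_size_range <- function(fragments, min_bp, max_bp) {
  min_bp <- as.numeric(min_bp); max_bp <- as.numeric(max_bp)
  if (is.na(min_bp) || is.na(max_bp) || min_bp > max_bp) {
    stop("invalid size range: min_bp must be <= max_bp", call. = FALSE)
  }
  fragments[fragments$length >= min_bp & fragments$length <= max_bp, ,
            drop = FALSE]
}

#' RRL summary statistics
#'
#' Summarises a size-selected fragment set the way an RRL design table does:
#' fragment count, fraction of the genome covered by the selected fragments,
#' megabases of unique tag sequence (one trimmed read length per fragment),
#' and the expected per-fragment tag coverage given a qualified pair count.
#'
#' @param fragments Selected fragment table (internal fragments).
#' @param genome_bp Total genome size in bp.
#' @param read_length Trimmed read length in bp (default 32).
#' @param qualified_pairs Number of quality-qualified read pairs, or NA.
#' @return A list of class `rrl_stats` with `n_fragments`, `genome_fraction`,
#'   `sampled_mb` and `tag_coverage`.
#' @export
rrl_summary <- function(fragments, genome_bp, read_length = 32L,
                        qualified_pairs = NA_real_) {
  if (is.data.frame(fragments)) {
    n <- nrow(fragments)
    selected_bp <- sum(as.numeric(fragments$length))
  } else {
    # also accept a bare fragment count for desk calculations
    n <- as.numeric(fragments)
    selected_bp <- NA_real_
  }
  genome_bp <- as.numeric(genome_bp)
  read_length <- as.numeric(read_length)
  if (is.na(read_length) || read_length <= 0) {
    stop("read_length must be > 0", call. = FALSE)
  }
  if (is.na(genome_bp) || genome_bp <= 0) {
    stop("genome_bp must be > 0", call. = FALSE)
  }
  if (n == 0) {
    stop("coverage undefined: zero selected fragments", call. = FALSE)
  }
  structure(list(
    n_fragments = n,
    genome_fraction = if (is.na(selected_bp)) NA_real_ else
      selected_bp / genome_bp,
    sampled_mb = n * read_length / 1e6,
    tag_coverage = as.numeric(qualified_pairs) / n
  ), class = "rrl_stats")
}

#' @export
print.rrl_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<rrl_stats> %d fragments | genome fraction %s | ",
           "sampled %.1f Mb | tag coverage %s\n"),
    as.integer(x$n_fragments),
    if (is.na(x$genome_fraction)) "NA" else
      sprintf("%.1f%%", 100 * x$genome_fraction),
    x$sampled_mb,
    if (is.na(x$tag_coverage)) "NA" else sprintf("%.1fX", x$tag_coverage)))
  invisible(x)
}

#' Extract fragment sequences
#'
#' @param genome Genome as accepted by [digest()].
#' @param fragments Fragment table.
#' @return A `DNAStringSet`, one entry per fragment.
#' @export
fragment_sequences <- function(genome, fragments) {
  dna <- as_dna_set(genome)
  if (nrow(fragments) == 0L) return(Biostrings::DNAStringSet())
  idx <- match(fragments$seq_id, names(dna))
  if (anyNA(idx)) stop("fragment seq_id absent from genome", call. = FALSE)
  res <- Biostrings::DNAStringSet(dna[idx],
                                  start = fragments$start,
                                  end = fragments$end)
  names(res) <- sprintf("%s:%d-%d", fragments$seq_id, fragments$start,
                        fragments$end)
  res
}

#' Write fragments as BED
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param fragments Fragment table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(
    chrom = fragments$seq_id,
    chromStart = fragments$start - 1L,
    chromEnd = fragments$end,
    name = sprintf("frag%06d", seq_len(nrow(fragments))),
    score = fragments$length,
    strand = "+",
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an RRL summary TSV
#'
#' One row per library, with the same columns an RRL design table reports.
#'
#' @param stats_list Named list of `rrl_stats` objects (name = library id).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rrl_summary_tsv <- function(stats_list, path) {
  rows <- do.call(rbind, lapply(names(stats_list), function(nm) {
    s <- stats_list[[nm]]
    data.frame(library = nm, n_fragments = s$n_fragments,
               genome_fraction = s$genome_fraction,
               sampled_mb = s$sampled_mb,
               tag_coverage = s$tag_coverage,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
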