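# Annotation of calls against gene models and repeats, breakpoint
# resolution from junction-spanning product sequences, and microhomology
# detection.

#' Load gene models from GFF3 or BED12
#'
#' GFF3 files are reduced to `gene` and `exon` features (transcript ids
#' taken from exon Parent attributes); BED12 blocks are expanded to exons
#' with the whole record as the gene span.
#'
#' @param path GFF3 (.gff/.gff3) or BED12 file.
#' @return `GRanges` with metadata columns `type` ("gene"/"exon"),
#'   `gene_id`, `transcript_id`.
#' @export
load_gene_models <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::import(path, format = "gff3")
    keep <- g[g$type %in% c("gene", "exon")]
    first_chr <- function(x, alt = NA_character_) {
      v <- as.character(x)
      ifelse(is.na(v) | !nzchar(v), alt, v)
    }
    parent <- vapply(as.list(keep$Parent), function(p) {
      if (length(p)) as.character(p[[1L]]) else NA_character_
    }, character(1))
    gene_id <- ifelse(keep$type == "gene",
                      first_chr(keep$ID), first_chr(keep$gene_id, parent))
    out <- GenomicRanges::granges(keep)
    out$type <- as.character(keep$type)
    out$gene_id <- gene_id
    out$transcript_id <- ifelse(keep$type == "exon", parent, NA_character_)
    return(out)
  }
  b <- rtracklayer::import(path, format = "bed")
  genes <- GenomicRanges::granges(b)
  genes$type <- "gene"
  genes$gene_id <- b$name
  genes$transcript_id <- NA_character_
  if (!is.null(b$blocks)) {
    ex <- GenomicRanges::GRanges(
      rep(GenomicRanges::seqnames(b), lengths(b$blocks)),
      IRanges::shift(unlist(b$blocks),
                     rep(BiocGenerics::start(b) - 1L, lengths(b$blocks))),
      strand = rep(GenomicRanges::strand(b), lengths(b$blocks)))
    ex$type <- "exon"
    ex$gene_id <- rep(b$name, lengths(b$blocks))
    ex$transcript_id <- rep(b$name, lengths(b$blocks))
    genes <- c(genes, ex)
  }
  genes
}

#' Load repeat annotations from BED
#'
#' Six-column BED with the repeat class in the name field (e.g. a converted
#' RepeatMasker table, or trf/dust tracks).
#'
#' @param path BED file.
#' @return `GRanges` with a `class` metadata column.
#' @export
load_repeats <- function(path) {
  b <- rtracklayer::import(path, format = "bed")
  out <- GenomicRanges::granges(b)
  out$class <- if (!is.null(b$name)) b$name else "repeat"
  out
}

#' Classify call locations relative to gene models
#'
#' A call is `exonic` when its interval intersects any exon, otherwise
#' `intronic` when it intersects a gene span, otherwise `intergenic`.
#' Contexts are mutually exclusive and exhaustive. Calls on sequences
#' absent from the annotation are classified intergenic with a warning.
#'
#' @param calls Call or locus table with `seq_id` and interval columns
#'   (`predicted_start`/`predicted_end` or `start`/`end`).
#' @param gene_models `GRanges` from [load_gene_models()].
#' @return `calls` with added `context`, `gene_ids`, `transcript_ids`.
#' @export
classify_location <- function(calls, gene_models) {
  a <- if ("predicted_start" %in% names(calls)) calls$predicted_start else
    calls$start
  b <- if ("predicted_end" %in% names(calls)) calls$predicted_end else
    calls$end
  gr <- GenomicRanges::GRanges(calls$seq_id, IRanges::IRanges(a, b))
  known <- as.character(calls$seq_id) %in%
    as.character(GenomeInfoDb::seqlevels(gene_models))
  if (any(!known)) {
    warning("calls on sequences absent from the annotation classified ",
            "intergenic: ", paste(unique(calls$seq_id[!known]),
                                  collapse = ", "))
  }
  exons <- gene_models[gene_models$type == "exon"]
  genes <- gene_models[gene_models$type == "gene"]
  suppressWarnings({
    hit_exon <- GenomicRanges::countOverlaps(gr, exons) > 0L
    hit_gene <- GenomicRanges::countOverlaps(gr, genes) > 0L
  })
  context <- ifelse(hit_exon, "exonic",
                    ifelse(hit_gene, "intronic", "intergenic"))
  join_hits <- function(feat, field) {
    suppressWarnings(ov <- GenomicRanges::findOverlaps(gr, feat))
    ids <- S4Vectors::mcols(feat)[[field]][S4Vectors::subjectHits(ov)]
    v <- tapply(ids, S4Vectors::queryHits(ov),
                function(z) paste(sort(unique(stats::na.omit(z))),
                                  collapse = ","))
    out <- rep(NA_character_, length(gr))
    out[as.integer(names(v))] <- as.character(v)
    out
  }
  calls$context <- context
  calls$gene_ids <- join_hits(genes, "gene_id")
  calls$transcript_ids <- join_hits(exons, "transcript_id")
  calls
}

#' Describe the effect of a deletion on one transcript
#'
#' For every exon intersected by the deletion interval, reports (in
#' transcript orientation) a full-exon `loss`, a `5' deletion` (the exon's
#' transcript-5' edge is removed), a `truncation` (the transcript-3' edge is
#' removed), or an `internal deletion`. A deletion confined to introns has
#' no effect.
#'
#' @param deletion List or one-row data.frame with `seq_id`, `start`, `end`
#'   (the removed interval, 1-based inclusive).
#' @param transcript_exons `GRanges` of one transcript's exons (any order;
#'   strand taken from the exons).
#' @return Character description, `"none"` if intron-only.
#' @export
exon_effect <- function(deletion, transcript_exons) {
  del <- IRanges::IRanges(deletion$start, deletion$end)
  strand <- as.character(GenomicRanges::strand(transcript_exons))[1L]
  ex <- transcript_exons[order(BiocGenerics::start(transcript_exons))]
  n_ex <- length(ex)
  ranks <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
  effects <- character(0)
  for (i in seq_len(n_ex)) {
    es <- BiocGenerics::start(ex)[i]; ee <- BiocGenerics::end(ex)[i]
    if (deletion$end < es || deletion$start > ee) next
    covers_left <- deletion$start <= es
    covers_right <- deletion$end >= ee
    # left genomic edge is the 5' edge on '+', the 3' edge on '-'
    covers5 <- if (strand == "-") covers_right else covers_left
    covers3 <- if (strand == "-") covers_left else covers_right
    kind <- if (covers5 && covers3) "loss"
    else if (covers5) "5' deletion"
    else if (covers3) "truncation"
    else "internal deletion"
    label <- if (ranks[i] == n_ex) "last exon" else
      paste0("exon ", ranks[i])
    effects <- c(effects, paste(kind, label))
  }
  if (length(effects) == 0L) "none" else paste(effects, collapse = "; ")
}

#' Repeat classes overlapping a call
#'
#' @param call List or one-row data.frame with `seq_id` and interval
#'   columns (`start`/`end` or `predicted_start`/`predicted_end`).
#' @param repeats `GRanges` from [load_repeats()].
#' @return Character vector of de-duplicated repeat classes;
#'   `"unannotated"` when none overlap.
#' @export
repeat_overlap <- function(call, repeats) {
  a <- if (!is.null(call$predicted_start)) call$predicted_start else
    call$start
  b <- if (!is.null(call$predicted_end)) call$predicted_end else call$end
  gr <- GenomicRanges::GRanges(call$seq_id, IRanges::IRanges(a, b))
  suppressWarnings(ov <- GenomicRanges::findOverlaps(gr, repeats))
  cls <- unique(repeats$class[S4Vectors::subjectHits(ov)])
  if (length(cls) == 0L) "unannotated" else sort(cls)
}

#' Resolve deletion breakpoints from a junction-spanning product
#'
#' Aligns a (Sanger-style) product sequence that spans the rearrangement
#' junction against the reference search region: the product's ends anchor
#' it by exact 20-mer match, and the junction split is the position
#' minimising total mismatches of the product prefix against the left
#' reference segment plus the product suffix against the right segment.
#' When junction microhomology makes several splits equivalent, the
#' left-aligned (smallest-coordinate) breakpoint pair is reported, the
#' usual normalisation convention.
#'
#' @param product Product sequence (character or `DNAString`).
#' @param reference Genome as accepted by [digest()].
#' @param seq_id Sequence the search region lies on.
#' @param region_start,region_end Search region (1-based inclusive),
#'   containing the true breakpoints and the product's anchor ends.
#' @param min_identity Minimum fraction of matching product bases for a
#'   successful resolution (default 0.95).
#' @param max_mh Maximum microhomology length searched (default 25).
#' @return List of class `breakpoint_resolution`: `status`
#'   (`resolved`/`failed`), `left_breakpoint`, `right_breakpoint` (deletion
#'   convention: bases `left+1 .. right` are deleted), `size`,
#'   `microhomology` (string, possibly empty), `identity`, and `reason`
#'   when failed.
#' @export
resolve_breakpoints <- function(product, reference, seq_id,
                                region_start, region_end,
                                min_identity = 0.95, max_mh = 25L) {
  ref <- as_dna_set(reference)
  chr <- ref[[seq_id]]
  region <- Biostrings::subseq(chr, region_start, region_end)
  prod <- as.character(product)
  P <- nchar(prod)
  fail <- function(reason) {
    structure(list(status = "failed", reason = reason,
                   left_breakpoint = NA_integer_,
                   right_breakpoint = NA_integer_, size = NA_integer_,
                   microhomology = NA_character_, identity = NA_real_),
              class = "breakpoint_resolution")
  }
  if (P < 40L) return(fail("product too short to anchor"))
  anchor <- function(kmer) {
    h <- Biostrings::matchPattern(kmer, region, fixed = TRUE)
    BiocGenerics::start(h)
  }
  a1 <- anchor(substr(prod, 1L, 20L))
  a2 <- anchor(substr(prod, P - 19L, P))
  if (length(a1) == 0L || length(a2) == 0L) {
    return(fail("product ends not found in search region"))
  }
  start_loc <- min(a1)                      # leftmost prefix anchor
  end_loc <- max(a2) + 19L                  # rightmost suffix anchor end
  if (end_loc <= start_loc) return(fail("anchors out of order"))
  refR <- as.character(Biostrings::subseq(region, start_loc, end_loc))
  R <- nchar(refR)
  D <- R - P
  if (D <= 0L) {
    return(fail("product not shorter than its reference extent; no deletion junction"))
  }
  pv <- strsplit(prod, "")[[1L]]
  rv <- strsplit(refR, "")[[1L]]
  pref_mm <- cumsum(pv != rv[seq_len(P)])             # product[1..k] vs ref
  suf_mm_vec <- pv != rv[seq_len(P) + D]              # product[i] vs ref[i+D]
  suf_after <- rev(cumsum(rev(suf_mm_vec)))           # mism. in i..P
  total <- c(suf_after[1L],                           # k = 0
             pref_mm + c(suf_after[-1L], 0))          # k = 1..P
  k <- which.min(total) - 1L                          # smallest k on ties
  identity <- (P - total[k + 1L]) / P
  if (identity < min_identity) {
    return(fail(sprintf("best split identity %.3f below %.3f", identity,
                        min_identity)))
  }
  left_bp <- region_start + start_loc - 1L + k - 1L
  right_bp <- left_bp + D
  mh <- detect_microhomology(reference, seq_id, left_bp, right_bp,
                             max_len = max_mh)
  structure(list(status = "resolved", left_breakpoint = left_bp,
                 right_breakpoint = right_bp, size = D,
                 microhomology = mh, identity = identity),
            class = "breakpoint_resolution")
}

#' @export
print.breakpoint_resolution <- function(x, ...) {
  if (x$status == "resolved") {
    cat(sprintf(
      "<breakpoint_resolution> %d-%d, size %d, microhomology '%s' (%.1f%%)\n",
      x$left_breakpoint, x$right_breakpoint, x$size, x$microhomology,
      100 * x$identity))
  } else {
    cat("<breakpoint_resolution> failed:", x$reason, "\n")
  }
  invisible(x)
}

#' Microhomology at a deletion junction
#'
#' Under the deletion convention (bases `left+1 .. right` removed), the
#' junction microhomology is the longest k <= `max_len` for which the first
#' k deleted bases equal the first k bases after the junction:
#' `ref[left+1 .. left+k] == ref[right+1 .. right+k]`.
#'
#' @param reference Genome as accepted by [digest()].
#' @param seq_id Sequence name.
#' @param left_breakpoint,right_breakpoint Deletion breakpoints.
#' @param max_len Maximum length searched (default 25).
#' @return The microhomology string (possibly empty).
#' @export
detect_microhomology <- function(reference, seq_id, left_breakpoint,
                                 right_breakpoint, max_len = 25L) {
  ref <- as_dna_set(reference)
  chr <- ref[[seq_id]]
  if (left_breakpoint < 1L || right_breakpoint <= left_breakpoint ||
      right_breakpoint > length(chr)) {
    stop("breakpoints out of sequence bounds", call. = FALSE)
  }
  kmax <- min(max_len, right_breakpoint - left_breakpoint,
              length(chr) - right_breakpoint)
  if (kmax < 1L) return("")
  a <- as.character(Biostrings::subseq(chr, left_breakpoint + 1L,
                                       left_breakpoint + kmax))
  b <- as.character(Biostrings::subseq(chr, right_breakpoint + 1L,
                                       right_breakpoint + kmax))
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  same <- av == bv
  k <- if (all(same)) kmax else which.min(same) - 1L
  substr(a, 1L, k)
}

#' Annotate a call table against gene models and repeats
#'
#' Convenience wrapper combining [classify_location()] and
#' [repeat_overlap()] into one annotation table.
#'
#' @param calls Call or locus table.
#' @param gene_models `GRanges` or NULL.
#' @param repeats `GRanges` or NULL.
#' @return `calls` with `context`/`gene_ids`/`transcript_ids` (when gene
#'   models given) and `repeat_classes` (comma-joined, when repeats given).
#' @export
annotate_calls <- function(calls, gene_models = NULL, repeats = NULL) {
  if (!is.null(gene_models)) calls <- classify_location(calls, gene_models)
  if (!is.null(repeats) && nrow(calls)) {
    calls$repeat_classes <- vapply(seq_len(nrow(calls)), function(i) {
      paste(repeat_overlap(calls[i, , drop = FALSE], repeats),
            collapse = ",")
    }, character(1))
  } else if (!is.null(repeats)) {
    calls$repeat_classes <- character(0)
  }
  calls
}
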