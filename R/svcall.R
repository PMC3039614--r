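# Discordant-pair clustering and the empirical discrimination rule.
#
# Discordant same-sequence pairs are grouped by SV class (too_long ->
# deletion, too_short -> insertion, inverted_orientation -> inversion
# breakpoint) and clustered by single linkage: two pairs join when their
# left-mate intervals overlap AND their right-mate intervals overlap.
# Clusters are then screened by per-side mean mapping quality and by the
# (span-size deviation) x support rule.

SV_CLASSES <- c(too_long = "DEL", too_short = "INS",
                inverted_orientation = "INV_BREAKPOINT")

# union-find with path compression; n is small (discordant pairs only)
uf_components <- function(n, edges_a, edges_b) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster discordant read pairs into SV candidates
#'
#' Single-linkage clustering within each SV class and sequence: two pairs
#' join iff their left footprints overlap and their right footprints overlap
#' (within `slop` bp, default 0). Pairs implying a rearrangement larger than
#' `max_sv_bp` (outer span above the cap) are discarded before clustering;
#' inter-chromosomal pairs never enter (they carry category `diff_chrom`).
#'
#' @param pairs Classified pair table ([classify_pairs()]).
#' @param max_sv_bp Maximum plausible SV size in bp (default 100000).
#' @param slop Footprint overlap tolerance in bp (default 0).
#' @return data.frame of clusters: `cluster_id`, `sv_class`, `seq_id`,
#'   footprint bounds, `predicted_start`/`predicted_end` (inner interval,
#'   bounded by the innermost footprint edges), `n` (supporting pairs),
#'   `span` (median member outer span), `aamq` (mean mapping quality over
#'   all member mates), per-side means `left_mapq`/`right_mapq`, and a
#'   `members` list column of pair ids.
#' @export
cluster_discordant <- function(pairs, max_sv_bp = 100000L, slop = 0L) {
  disc <- pairs[pairs$category %in% names(SV_CLASSES), , drop = FALSE]
  disc <- disc[is.na(disc$outer_span) | disc$outer_span <= max_sv_bp, ,
               drop = FALSE]
  empty <- data.frame(
    cluster_id = character(0), sv_class = character(0),
    seq_id = character(0), left_fp_start = integer(0),
    left_fp_end = integer(0), right_fp_start = integer(0),
    right_fp_end = integer(0), predicted_start = integer(0),
    predicted_end = integer(0), n = integer(0), span = numeric(0),
    aamq = numeric(0), left_mapq = numeric(0), right_mapq = numeric(0),
    stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(disc) == 0L) return(empty)

  # orient each pair: left mate = smaller start
  swap <- disc$start2 < disc$start1
  ls <- ifelse(swap, disc$start2, disc$start1)
  le <- ifelse(swap, disc$end2, disc$end1)
  lq <- ifelse(swap, disc$mapq2, disc$mapq1)
  rs <- ifelse(swap, disc$start1, disc$start2)
  re <- ifelse(swap, disc$end1, disc$end2)
  rq <- ifelse(swap, disc$mapq1, disc$mapq2)
  sv_class <- unname(SV_CLASSES[as.character(disc$category)])

  out <- list()
  for (key in unique(paste(sv_class, disc$seq_id1))) {
    sel <- which(paste(sv_class, disc$seq_id1) == key)
    irl <- IRanges::IRanges(ls[sel], le[sel])
    irr <- IRanges::IRanges(rs[sel], re[sel])
    ovl <- IRanges::findOverlaps(irl, irl, maxgap = slop)
    ovr <- IRanges::findOverlaps(irr, irr, maxgap = slop)
    el <- paste(S4Vectors::queryHits(ovl), S4Vectors::subjectHits(ovl))
    er <- paste(S4Vectors::queryHits(ovr), S4Vectors::subjectHits(ovr))
    common <- intersect(el, er)
    ab <- do.call(rbind, strsplit(common, " "))
    comp <- uf_components(length(sel), as.integer(ab[, 1L]),
                          as.integer(ab[, 2L]))
    for (cc in unique(comp)) {
      mem <- sel[comp == cc]
      out[[length(out) + 1L]] <- data.frame(
        sv_class = sv_class[mem[1L]],
        seq_id = disc$seq_id1[mem[1L]],
        left_fp_start = min(ls[mem]), left_fp_end = max(le[mem]),
        right_fp_start = min(rs[mem]), right_fp_end = max(re[mem]),
        n = length(mem),
        span = stats::median(disc$outer_span[mem]),
        aamq = mean(c(lq[mem], rq[mem])),
        left_mapq = mean(lq[mem]), right_mapq = mean(rq[mem]),
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- list(disc$pair_id[mem])
    }
  }
  res <- do.call(rbind, out)
  # inner interval between the footprints; with heavily overlapping mates
  # (small insertion spans) the innermost edges can cross, so order them
  res$predicted_start <- pmin(res$left_fp_end, res$right_fp_start)
  res$predicted_end <- pmax(res$left_fp_end, res$right_fp_start)
  # deterministic order regardless of input permutation
  res <- res[order(res$seq_id, res$sv_class, res$left_fp_start,
                   res$right_fp_start, res$n), , drop = FALSE]
  res$cluster_id <- sprintf("cl%05d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("cluster_id", names(empty)[-1L])]
}

#' Filter clusters by per-side mean mapping quality
#'
#' Both footprint sides must reach the threshold, the stricter reading of
#' requiring "both ends" to map with concordant-like quality. Typical
#' thresholds are 60 (stringent) and 35 (relaxed).
#'
#' @param clusters Cluster table from [cluster_discordant()].
#' @param threshold Minimum per-side mean mapping quality.
#' @return The retained clusters.
#' @export
mapq_filter <- function(clusters, threshold = 60) {
  clusters[clusters$left_mapq >= threshold &
             clusters$right_mapq >= threshold, , drop = FALSE]
}

#' The (span-size deviation) x support discrimination rule
#'
#' Size-selection leakage lets a small fraction of fragments slip past the
#' gel window, producing spurious discordant clusters whose spans deviate
#' only modestly from the concordance thresholds. The rule compensates by
#' requiring `deviation x n > threshold` (strict), where the deviation is
#' measured from the concordance thresholds: `span - 220` for deletions and
#' `100 - span` for insertions.
#'
#' The rule was calibrated on deletion spans of 220-720 bp, the range gel
#' artifacts can reach; clusters beyond 720 bp are still scored (confirmed
#' rearrangements exist there) but are flagged `rule_in_window = FALSE` as
#' lower-confidence, since independent confirmation above the window was
#' mixed. Inversion-breakpoint clusters get outcome `not_applicable`.
#'
#' @param clusters Cluster table (DEL/INS/INV_BREAKPOINT rows).
#' @param threshold Rule threshold (default 500, strict inequality).
#' @param del_baseline,ins_baseline Concordance thresholds (220 / 100 bp).
#' @param del_valid_max Upper end of the calibrated deletion window (720).
#' @param ins_min Minimum meaningful insertion span (32 bp, one read).
#' @return `clusters` with `rule_deviation`, `rule_score`, `rule_outcome`
#'   (`pass`/`fail`/`not_applicable`) and `rule_in_window` columns.
#' @export
abundance_rule <- function(clusters, threshold = 500,
                           del_baseline = 220, del_valid_max = 720,
                           ins_baseline = 100, ins_min = 32) {
  dev <- rep(NA_real_, nrow(clusters))
  in_window <- rep(NA, nrow(clusters))
  del <- clusters$sv_class == "DEL"
  ins <- clusters$sv_class == "INS"
  if (any(del & clusters$span <= del_baseline)) {
    stop("inconsistent cluster: deletion span <= ", del_baseline,
         call. = FALSE)
  }
  if (any(ins & (clusters$span >= ins_baseline | clusters$span < ins_min))) {
    stop("inconsistent cluster: insertion span outside [", ins_min, ",",
         ins_baseline, ")", call. = FALSE)
  }
  dev[del] <- clusters$span[del] - del_baseline
  dev[ins] <- ins_baseline - clusters$span[ins]
  in_window[del] <- clusters$span[del] <= del_valid_max
  in_window[ins] <- TRUE
  score <- dev * clusters$n
  outcome <- ifelse(is.na(score), "not_applicable",
                    ifelse(score > threshold, "pass", "fail"))
  clusters$rule_deviation <- dev
  clusters$rule_score <- score
  clusters$rule_outcome <- outcome
  clusters$rule_in_window <- in_window
  clusters
}

#' Promote clusters to SV calls
#'
#' Adds the class-specific size estimate relative to the modal insert size
#' (deletion: span minus modal insert; insertion: modal insert minus span)
#' and a pool identifier.
#'
#' @param clusters Cluster table with rule columns ([abundance_rule()]).
#' @param modal_insert Modal concordant insert size in bp.
#' @param pool_id Pool (library) identifier.
#' @return Call table, one row per cluster.
#' @export
make_calls <- function(clusters, modal_insert, pool_id = "pool1") {
  size <- rep(NA_real_, nrow(clusters))
  del <- clusters$sv_class == "DEL"
  ins <- clusters$sv_class == "INS"
  size[del] <- clusters$span[del] - modal_insert
  size[ins] <- modal_insert - clusters$span[ins]
  clusters$size_estimate <- size
  clusters$pool_id <- rep(pool_id, nrow(clusters))
  clusters
}

#' Prioritize rule-screened candidates for confirmation
#'
#' Mirrors the confirmation triage: (i) per-side mean mapping quality at
#' least `mapq_threshold`; (ii) a flag for clusters whose whole footprint
#' lies within a single annotated exon or gene; (iii) primer feasibility
#' approximated as at least `flank_bp` of non-N reference on both sides of
#' the predicted interval. Candidates are ordered by the two flags and then
#' by decreasing mean mapping quality.
#'
#' @param clusters Cluster/call table.
#' @param gene_models `GRanges` of gene models ([load_gene_models()]), or
#'   NULL to skip the feature flag.
#' @param reference Genome (as accepted by [digest()]), or NULL to skip the
#'   flank check.
#' @param flank_bp Required clean flank, bp (default 200).
#' @param mapq_threshold Minimum per-side mean mapping quality (default 60).
#' @return The qualifying clusters, ranked, with `in_feature` and
#'   `clean_flanks` columns.
#' @export
prioritize <- function(clusters, gene_models = NULL, reference = NULL,
                       flank_bp = 200L, mapq_threshold = 60) {
  cand <- mapq_filter(clusters, mapq_threshold)
  if (nrow(cand) == 0L) {
    cand$in_feature <- logical(0)
    cand$clean_flanks <- logical(0)
    return(cand)
  }
  fp <- GenomicRanges::GRanges(
    cand$seq_id, IRanges::IRanges(cand$left_fp_start, cand$right_fp_end))
  if (!is.null(gene_models)) {
    feat <- gene_models[gene_models$type %in% c("gene", "exon")]
    within <- GenomicRanges::countOverlaps(fp, feat, type = "within") > 0L
    cand$in_feature <- within
  } else {
    cand$in_feature <- NA
  }
  if (!is.null(reference)) {
    ref <- as_dna_set(reference)
    clean <- vapply(seq_len(nrow(cand)), function(i) {
      s <- ref[[cand$seq_id[i]]]
      a <- cand$predicted_start[i]; b <- cand$predicted_end[i]
      if (a - flank_bp < 1L || b + flank_bp > length(s)) return(FALSE)
      lf <- Biostrings::subseq(s, a - flank_bp, a - 1L)
      rf <- Biostrings::subseq(s, b + 1L, b + flank_bp)
      Biostrings::countPattern("N", lf, fixed = TRUE) == 0L &&
        Biostrings::countPattern("N", rf, fixed = TRUE) == 0L
    }, logical(1))
    cand$clean_flanks <- clean
  } else {
    cand$clean_flanks <- NA
  }
  ord <- order(!(cand$in_feature %in% TRUE), !(cand$clean_flanks %in% TRUE),
               -cand$aamq)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Deletion length from its breakpoints
#'
#' Under the breakpoint convention used throughout (a deletion with
#' breakpoints `(left, right)` removes reference bases `left+1 .. right`),
#' the deleted length is `right - left`.
#'
#' @param left_breakpoint,right_breakpoint 1-based coordinates on one
#'   sequence, `right > left`.
#' @return Length in bp.
#' @examples
#' deletion_length(55356006, 55357163)  # 1157
#' @export
deletion_length <- function(left_breakpoint, right_breakpoint) {
  if (any(right_breakpoint <= left_breakpoint)) {
    stop("right breakpoint must exceed left breakpoint", call. = FALSE)
  }
  right_breakpoint - left_breakpoint
}
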