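# Cross-pool analysis: merge per-pool calls into loci, count sharing
# partitions, and summarise the size spectrum.

#' Merge calls across pools into SV loci
#'
#' Calls of the same class merge into one locus when their predicted
#' intervals overlap reciprocally by at least `reciprocal_overlap` in both
#' directions (single linkage). Presence is the union of pool ids; per-pool
#' support is summed.
#'
#' @param calls Call table(s) (rbind of [make_calls()] output across pools;
#'   must carry `pool_id`).
#' @param reciprocal_overlap Minimum reciprocal overlap fraction (default
#'   0.5).
#' @return Locus table: `locus_id`, `sv_class`, `seq_id`, `start`, `end`,
#'   `size` (median member size estimate), `n_calls`, `presence`
#'   (comma-joined sorted pool ids), and a `support` list column of named
#'   per-pool support.
#' @export
merge_across_pools <- function(calls, reciprocal_overlap = 0.5) {
  empty <- data.frame(locus_id = character(0), sv_class = character(0),
                      seq_id = character(0), start = integer(0),
                      end = integer(0), size = numeric(0),
                      n_calls = integer(0), presence = character(0),
                      stringsAsFactors = FALSE)
  empty$support <- list()
  if (nrow(calls) == 0L) return(empty)
  out <- list()
  for (key in unique(paste(calls$sv_class, calls$seq_id))) {
    sel <- which(paste(calls$sv_class, calls$seq_id) == key)
    ir <- IRanges::IRanges(calls$predicted_start[sel],
                           calls$predicted_end[sel])
    ov <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(ir[qh], ir[sh]))
    recip <- w >= reciprocal_overlap * IRanges::width(ir[qh]) &
      w >= reciprocal_overlap * IRanges::width(ir[sh])
    comp <- uf_components(length(sel), qh[recip], sh[recip])
    for (cc in unique(comp)) {
      mem <- sel[comp == cc]
      sup <- tapply(calls$n[mem], calls$pool_id[mem], sum)
      row <- data.frame(
        sv_class = calls$sv_class[mem[1L]],
        seq_id = calls$seq_id[mem[1L]],
        start = min(calls$predicted_start[mem]),
        end = max(calls$predicted_end[mem]),
        size = stats::median(calls$size_estimate[mem]),
        n_calls = length(mem),
        presence = paste(sort(unique(calls$pool_id[mem])), collapse = ","),
        stringsAsFactors = FALSE)
      row$support <- list(sup)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start, res$sv_class), , drop = FALSE]
  res$locus_id <- sprintf("locus%05d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("locus_id", setdiff(names(res), "locus_id"))]
}

#' Sharing partition over pools
#'
#' Exact counts for every non-empty subset of pools (the cells of a Venn
#' diagram), plus per-pool totals and the percentage of each pool's loci
#' that are pool-specific.
#'
#' @param loci Locus table from [merge_across_pools()].
#' @param pools Character vector of all pool ids (at most 6).
#' @return List of class `sharing_partition`: `cells` (data.frame `subset`,
#'   `count`, one row per non-empty subset), `per_pool` (named totals),
#'   `percent_specific` (named), `n_loci`.
#' @export
sharing_partition <- function(loci, pools) {
  pools <- as.character(pools)
  if (length(pools) > 6L) {
    stop("sharing_partition supports at most 6 pools", call. = FALSE)
  }
  k <- length(pools)
  subsets <- character(0)
  for (m in seq_len(k)) {
    cmb <- utils::combn(sort(pools), m)
    subsets <- c(subsets, apply(cmb, 2L, paste, collapse = ","))
  }
  norm <- function(p) paste(sort(strsplit(p, ",")[[1L]]), collapse = ",")
  obs <- vapply(loci$presence, norm, character(1), USE.NAMES = FALSE)
  if (nrow(loci) && !all(obs %in% subsets)) {
    stop("locus presence includes a pool not listed in `pools`",
         call. = FALSE)
  }
  counts <- vapply(subsets, function(s) sum(obs == s), integer(1))
  per_pool <- vapply(pools, function(p) {
    sum(vapply(obs, function(o) p %in% strsplit(o, ",")[[1L]], logical(1)))
  }, integer(1))
  specific <- vapply(pools, function(p) sum(obs == p), integer(1))
  structure(list(
    cells = data.frame(subset = subsets, count = unname(counts),
                       stringsAsFactors = FALSE),
    per_pool = per_pool,
    percent_specific = ifelse(per_pool > 0, 100 * specific / per_pool, NA),
    n_loci = nrow(loci)
  ), class = "sharing_partition")
}

#' @export
print.sharing_partition <- function(x, ...) {
  cat(sprintf("<sharing_partition> %d loci over %d pools\n", x$n_loci,
              length(x$per_pool)))
  nz <- x$cells[x$cells$count > 0L, , drop = FALSE]
  for (i in seq_len(nrow(nz))) {
    cat(sprintf("  {%s}: %d\n", nz$subset[i], nz$count[i]))
  }
  invisible(x)
}

#' Size distribution of SV loci
#'
#' Bin counts over the locus size estimates plus cumulative fractions below
#' given thresholds (defaults 500 bp and 1 kb).
#'
#' @param sizes Numeric sizes in bp, or a locus table with a `size` column.
#' @param breaks Bin edges in bp.
#' @param thresholds Thresholds for cumulative fractions.
#' @return List with `bins` (data.frame `bin`, `count`) and `frac_below`
#'   (named fractions; NA when there are no sizes).
#' @export
size_distribution <- function(sizes,
                              breaks = c(0, 100, 250, 500, 1000, 2500,
                                         5000, 10000, Inf),
                              thresholds = c(500, 1000)) {
  if (is.data.frame(sizes)) sizes <- sizes$size
  sizes <- sizes[!is.na(sizes)]
  cuts <- cut(sizes, breaks = breaks, right = FALSE)
  bins <- data.frame(bin = levels(cuts),
                     count = as.integer(table(cuts)),
                     stringsAsFactors = FALSE)
  frac <- vapply(thresholds, function(t) {
    if (length(sizes) == 0L) NA_real_ else mean(sizes < t)
  }, numeric(1))
  names(frac) <- paste0("<", thresholds, "bp")
  list(bins = bins, frac_below = frac)
}

#' Write the sharing partition as JSON
#'
#' @param partition A `sharing_partition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  cells <- stats::setNames(as.list(partition$cells$count),
                           partition$cells$subset)
  jsonlite::write_json(
    list(n_loci = partition$n_loci, cells = cells,
         per_pool = as.list(partition$per_pool),
         percent_specific = as.list(partition$percent_specific)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the locus table as TSV
#'
#' @param loci Locus table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_locus_tsv <- function(loci, path) {
  flat <- loci[, setdiff(names(loci), "support"), drop = FALSE]
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
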