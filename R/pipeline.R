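# Pipeline orchestration: one configuration drives digest -> read QC ->
# mapping -> classification -> clustering -> rule screening -> cross-pool
# merge -> annotation, with every stage's counts logged so the filtering
# accounting of a run can be audited.

#' Pipeline configuration
#'
#' All thresholds default to the values the analysis was designed around:
#' concordance window 100-220 bp, rule threshold 500 with deletion validity
#' window 220-720 bp, insertion window 32-100 bp, mapping-quality threshold
#' 60 (relaxed alternative 35), 100 kb cluster cap, reciprocal merge
#' overlap 0.5.
#'
#' @param reference Reference genome: FASTA path, named character vector or
#'   `DNAStringSet`.
#' @param pools List of pool inputs; each element a list with `pool_id` and
#'   either `fastq1`/`fastq2` paths or in-memory `reads1`/`reads2` tables.
#' @param gene_models,repeats Optional annotation file paths (GFF3/BED12,
#'   BED) or `GRanges`.
#' @param output_dir Output directory, or NULL to skip file output.
#' @param span_min,span_max Concordance window, bp.
#' @param rule_threshold,del_valid_max,ins_min Rule parameters.
#' @param mapq_threshold Cluster mapping-quality threshold (60 or 35).
#' @param cluster_slop Footprint overlap tolerance, bp.
#' @param max_sv_bp Cluster size cap, bp.
#' @param merge_overlap Reciprocal overlap for cross-pool merging.
#' @param tag,trim_to,min_q Read qualification parameters.
#' @param seed Seed recorded with the run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, pools, gene_models = NULL,
                            repeats = NULL, output_dir = NULL,
                            span_min = 100L, span_max = 220L,
                            rule_threshold = 500, del_valid_max = 720,
                            ins_min = 32, mapq_threshold = 60,
                            cluster_slop = 0L, max_sv_bp = 100000L,
                            merge_overlap = 0.5, tag = "CT",
                            trim_to = 32L, min_q = 20L, seed = 1L) {
  num_pos <- c(span_min = span_min, span_max = span_max,
               rule_threshold = rule_threshold,
               del_valid_max = del_valid_max, ins_min = ins_min,
               mapq_threshold = mapq_threshold, max_sv_bp = max_sv_bp,
               merge_overlap = merge_overlap, trim_to = trim_to,
               min_q = min_q)
  bad <- names(num_pos)[!is.finite(num_pos) | num_pos <= 0]
  if (length(bad)) {
    stop("config error at field ", bad[1L], ": must be a positive number",
         call. = FALSE)
  }
  if (span_min >= span_max) {
    stop("config error at field span_min: must be below span_max",
         call. = FALSE)
  }
  for (p in pools) {
    if (is.null(p$pool_id)) {
      stop("config error at field pools: every pool needs a pool_id",
           call. = FALSE)
    }
    for (f in c("fastq1", "fastq2")) {
      if (!is.null(p[[f]]) && !file.exists(p[[f]])) {
        stop("missing input file for pool ", p$pool_id, ": ", p[[f]],
             call. = FALSE)
      }
    }
  }
  if (is.character(reference) && length(reference) == 1L &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", reference) &&
      !file.exists(reference)) {
    stop("missing input file: ", reference, call. = FALSE)
  }
  structure(list(reference = reference, pools = pools,
                 gene_models = gene_models, repeats = repeats,
                 output_dir = output_dir, span_min = span_min,
                 span_max = span_max, rule_threshold = rule_threshold,
                 del_valid_max = del_valid_max, ins_min = ins_min,
                 mapq_threshold = mapq_threshold,
                 cluster_slop = cluster_slop, max_sv_bp = max_sv_bp,
                 merge_overlap = merge_overlap, tag = tag,
                 trim_to = trim_to, min_q = min_q, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("config error at field ", unknown[1L], ": unknown field",
         call. = FALSE)
  }
  do.call(pipeline_config, y)
}

#' Run the whole discovery pipeline
#'
#' For every pool: qualify read pairs, map with the built-in unique-best
#' mapper, classify pairs, cluster discordant pairs, apply the
#' mapping-quality and abundance-rule screens, and promote clusters to
#' calls. Calls are then merged across pools and (optionally) annotated.
#' Deterministic given the inputs and config.
#'
#' @param config A [pipeline_config()].
#' @return List with per-pool results (`qc`, `pairs` summary, `clusters`,
#'   `calls`, `modal_insert`), merged `loci`, `partition` (>= 2 pools),
#'   `annotated` (when annotations were given), and the run `log`
#'   (data.frame). Files are written under `config$output_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ref <- as_dna_set(config$reference)
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  log <- list()
  note <- function(pool, stage, metric, value) {
    log[[length(log) + 1L]] <<- data.frame(
      pool = pool, stage = stage, metric = metric, value = value,
      stringsAsFactors = FALSE)
  }
  pool_res <- list()
  all_calls <- list()
  for (p in config$pools) {
    pid <- p$pool_id
    reads1 <- if (!is.null(p$reads1)) p$reads1 else read_fastq(p$fastq1)
    reads2 <- if (!is.null(p$reads2)) p$reads2 else read_fastq(p$fastq2)
    note(pid, "input", "raw_pairs", nrow(reads1))
    fp <- filter_pairs(reads1, reads2, tag = config$tag,
                       trim_to = config$trim_to, min_q = config$min_q)
    for (k in names(unclass(fp$report))) {
      note(pid, "readqc", k, fp$report[[k]])
    }
    if (nrow(fp$pairs1) > 0L) {
      a1 <- map_reads_unique(fp$pairs1$seq, ref)
      a2 <- map_reads_unique(fp$pairs2$seq, ref)
      pairs <- pair_alignments(a1, a2,
                               pair_id = sub("/1$", "", fp$pairs1$id),
                               read_length = config$trim_to)
    } else {
      a0 <- map_reads_unique(character(0), ref)
      pairs <- pair_alignments(a0, a0, pair_id = character(0),
                               read_length = config$trim_to)
    }
    pairs <- classify_pairs(pairs, config$span_min, config$span_max)
    catsum <- category_summary(pairs)
    for (i in seq_len(nrow(catsum))) {
      note(pid, "classify", catsum$category[i], catsum$count[i])
    }
    hist <- insert_size_histogram(pairs)
    mi <- modal_insert(hist, config$span_min, config$span_max)
    clusters <- cluster_discordant(pairs, max_sv_bp = config$max_sv_bp,
                                   slop = config$cluster_slop)
    note(pid, "cluster", "clusters", nrow(clusters))
    kept <- mapq_filter(clusters, config$mapq_threshold)
    note(pid, "mapq_filter", "retained", nrow(kept))
    kept <- abundance_rule(kept, threshold = config$rule_threshold,
                           del_valid_max = config$del_valid_max,
                           ins_min = config$ins_min)
    calls <- make_calls(kept, mi, pool_id = pid)
    note(pid, "rule", "pass", sum(calls$rule_outcome == "pass"))
    note(pid, "rule", "fail", sum(calls$rule_outcome == "fail"))
    note(pid, "rule", "not_applicable",
         sum(calls$rule_outcome == "not_applicable"))
    pool_res[[pid]] <- list(qc = fp$report, category_summary = catsum,
                            insert_histogram = hist, modal_insert = mi,
                            clusters = clusters, calls = calls)
    all_calls[[pid]] <- calls
    if (!is.null(outdir)) {
      write_qc_report(fp$report, file.path(outdir,
                                           paste0(pid, "_qc.tsv")))
      utils::write.table(catsum,
                         file.path(outdir, paste0(pid, "_categories.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(hist,
                         file.path(outdir, paste0(pid, "_inserts.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_calls(calls, file.path(outdir, paste0(pid, ".vcf")),
                  format = "vcf", ref_lengths = stats::setNames(
                    BiocGenerics::width(ref), names(ref)))
      write_calls(calls, file.path(outdir, paste0(pid, ".bedpe")),
                  format = "bedpe")
    }
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  # cross-pool sharing is computed over rule-validated calls only
  loci <- merge_across_pools(calls[calls$rule_outcome == "pass", ,
                                   drop = FALSE],
                             config$merge_overlap)
  note("-", "merge", "loci", nrow(loci))
  partition <- NULL
  if (length(config$pools) >= 2L) {
    partition <- sharing_partition(
      loci, vapply(config$pools, `[[`, character(1), "pool_id"))
  }
  annotated <- NULL
  gm <- config$gene_models
  if (is.character(gm)) gm <- load_gene_models(gm)
  rp <- config$repeats
  if (is.character(rp)) rp <- load_repeats(rp)
  if (!is.null(gm) || !is.null(rp)) {
    annotated <- annotate_calls(loci, gm, rp)
  }
  log <- do.call(rbind, log)
  if (!is.null(outdir)) {
    write_locus_tsv(loci, file.path(outdir, "loci.tsv"))
    if (!is.null(partition)) {
      write_partition_json(partition, file.path(outdir, "sharing.json"))
    }
    if (!is.null(annotated)) {
      write_locus_tsv(annotated, file.path(outdir, "annotation.tsv"))
    }
    utils::write.table(log, file.path(outdir, "run_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(pools = pool_res, calls = calls, loci = loci,
                 partition = partition, annotated = annotated, log = log,
                 config = config))
}

VCF_ALT <- c(DEL = "<DEL>", INS = "<INS>", INV_BREAKPOINT = "<INV>",
             INV = "<INV>")

#' Write SV calls as VCF 4.2 or BEDPE
#'
#' VCF records use symbolic alleles with INFO keys SVTYPE, END, SVLEN
#' (negative for deletions), SUPPORT (n), SPAN, AAMQ, RULE_SCORE,
#' RULE=pass|fail|na and POOL. Coordinates are the call's predicted
#' interval (1-based inclusive internally; BEDPE converts to 0-based
#' half-open). Output is deterministic: records sorted by sequence and
#' position.
#'
#' @param calls Call table ([make_calls()]), may be empty.
#' @param path Output file.
#' @param format "vcf" or "bedpe".
#' @param ref_lengths Named vector of sequence lengths for VCF contig
#'   header lines (optional).
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("vcf", "bedpe"),
                        ref_lengths = NULL) {
  format <- match.arg(format)
  ord <- order(calls$seq_id, calls$predicted_start, calls$predicted_end,
               calls$sv_class)
  calls <- calls[ord, , drop = FALSE]
  if (any(is.na(calls$predicted_start)) ||
      any(calls$predicted_end < calls$predicted_start)) {
    stop("unsortable records: missing or inverted coordinates",
         call. = FALSE)
  }
  if (format == "bedpe") {
    if (nrow(calls) == 0L) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    rows <- data.frame(
      chrom1 = calls$seq_id, start1 = calls$left_fp_start - 1L,
      end1 = calls$left_fp_end,
      chrom2 = calls$seq_id, start2 = calls$right_fp_start - 1L,
      end2 = calls$right_fp_end,
      name = paste0(calls$pool_id, ":", calls$cluster_id),
      score = calls$rule_score, strand1 = "+", strand2 = "-",
      sv_class = calls$sv_class, n = calls$n, span = calls$span,
      aamq = calls$aamq, rule = calls$rule_outcome,
      stringsAsFactors = FALSE)
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rrlsv",
    if (!is.null(ref_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(ref_lengths),
              as.integer(ref_lengths))
    },
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion breakpoint\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the predicted interval\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length (negative for deletions)\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting discordant pairs\">",
    "##INFO=<ID=SPAN,Number=1,Type=Float,Description=\"Consensus outer span\">",
    "##INFO=<ID=AAMQ,Number=1,Type=Float,Description=\"Mean mapping quality of member mates\">",
    "##INFO=<ID=RULE_SCORE,Number=1,Type=Float,Description=\"(span deviation) x support\">",
    "##INFO=<ID=RULE,Number=1,Type=String,Description=\"Rule outcome: pass, fail or na\">",
    "##INFO=<ID=POOL,Number=1,Type=String,Description=\"Pool of origin\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls)) {
    svtype <- ifelse(calls$sv_class == "INV_BREAKPOINT", "INV",
                     calls$sv_class)
    svlen <- ifelse(svtype == "DEL", -round(calls$size_estimate),
                    ifelse(svtype == "INS", round(calls$size_estimate), 0))
    rule <- c(pass = "pass", fail = "fail",
              not_applicable = "na")[calls$rule_outcome]
    info <- sprintf(
      "SVTYPE=%s;END=%d;SVLEN=%d;SUPPORT=%d;SPAN=%s;AAMQ=%s;RULE_SCORE=%s;RULE=%s;POOL=%s",
      svtype, calls$predicted_end, as.integer(svlen), calls$n,
      num_str(calls$span), num_str(calls$aamq),
      num_str(calls$rule_score), rule, calls$pool_id)
    filter <- ifelse(rule == "pass", "PASS",
                     ifelse(rule == "fail", "LowScore", "."))
    body <- sprintf("%s\t%d\t%s\tN\t%s\t%s\t%s\t%s",
                    calls$seq_id, calls$predicted_start,
                    paste0(calls$pool_id, ":", calls$cluster_id),
                    VCF_ALT[calls$sv_class], num_str(calls$aamq), filter,
                    info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

num_str <- function(x) {
  out <- ifelse(is.na(x), ".", formatC(x, format = "g", digits = 10))
  sub("^\\s+", "", out)
}

#' Parse a VCF written by [write_calls()]
#'
#' Restores the call fields carried in INFO; together with [write_calls()]
#' this round-trips (write -> read -> write is byte-identical).
#'
#' @param path VCF file.
#' @return Call table with the columns used by [write_calls()].
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.frame(seq_id = character(0), predicted_start = integer(0),
                      cluster_id = character(0), sv_class = character(0),
                      predicted_end = integer(0),
                      size_estimate = numeric(0), n = integer(0),
                      span = numeric(0), aamq = numeric(0),
                      rule_score = numeric(0), rule_outcome = character(0),
                      pool_id = character(0), stringsAsFactors = FALSE)
  if (length(body) == 0L) return(empty)
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    sub(paste0("^;?", key, "="), "", m)
  }
  info <- f[, 8L]
  svtype <- info_get(info, "SVTYPE")
  svlen <- as.numeric(info_get(info, "SVLEN"))
  rule <- info_get(info, "RULE")
  data.frame(
    seq_id = f[, 1L], predicted_start = as.integer(f[, 2L]),
    cluster_id = sub("^[^:]*:", "", f[, 3L]),
    sv_class = ifelse(svtype == "INV", "INV_BREAKPOINT", svtype),
    predicted_end = as.integer(info_get(info, "END")),
    size_estimate = abs(svlen),
    n = as.integer(info_get(info, "SUPPORT")),
    span = as.numeric(info_get(info, "SPAN")),
    aamq = as.numeric(info_get(info, "AAMQ")),
    rule_score = suppressWarnings(as.numeric(info_get(info, "RULE_SCORE"))),
    rule_outcome = ifelse(rule == "na", "not_applicable", rule),
    pool_id = info_get(info, "POOL"),
    stringsAsFactors = FALSE)
}
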