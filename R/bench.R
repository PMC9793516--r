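# Truth-set benchmarking: classify a comparison callset against a baseline
# and summarize precision / recall / F1 / genotype concordance.

#' Summarize a bench classification
#'
#' @param tp_base,tp_comp,fp,fn,filtered Counts.
#' @param gt_matches,gt_total TP pairs with agreeing genotypes / TP pairs
#'   with comparable genotypes.
#' @return A `bench_summary` list with counts and derived rates. Rates with
#'   an empty denominator are `NA` (missing), never 0.
#' @export
bench_summary <- function(tp_base, tp_comp, fp, fn, filtered = 0,
                          gt_matches = NA, gt_total = NA) {
  base_cnt <- tp_base + fn
  call_cnt <- tp_comp + fp
  precision <- if (call_cnt > 0) tp_comp / call_cnt else NA_real_
  recall <- if (base_cnt > 0) tp_base / base_cnt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * (recall * precision) / (recall + precision) else NA_real_
  gt_concordance <- if (!is.na(gt_total) && gt_total > 0)
    gt_matches / gt_total else NA_real_
  structure(list(
    tp_base = tp_base, tp_comp = tp_comp, fp = fp, fn = fn,
    base_cnt = base_cnt, call_cnt = call_cnt, filtered = filtered,
    precision = precision, recall = recall, f1 = f1,
    gt_concordance = gt_concordance
  ), class = "bench_summary")
}

#' @export
print.bench_summary <- function(x, ...) {
  cat("SV benchmarking summary\n")
  cat(sprintf("  TP-base: %d   TP-comp: %d   FP: %d   FN: %d   filtered: %d\n",
              x$tp_base, x$tp_comp, x$fp, x$fn, x$filtered))
  cat(sprintf("  base cnt: %d   call cnt: %d\n", x$base_cnt, x$call_cnt))
  cat(sprintf("  precision: %s   recall: %s   F1: %s   GT concordance: %s\n",
              fmt_num(x$precision), fmt_num(x$recall), fmt_num(x$f1),
              fmt_num(x$gt_concordance)))
  invisible(x)
}

#' Benchmark a comparison VCF against a baseline VCF
#'
#' Zips the two callsets, chunks the stream, builds the NxM match matrix per
#' chunk, assigns matches (single-best unless `params$multimatch`), and
#' partitions all filtered input records into TP-base / TP-comp / FP / FN.
#'
#' @param base,comp Paths to sorted VCFs or `sv_records` tables.
#' @param reference `DNAStringSet` or FASTA path; required when
#'   `params$pctseq > 0`.
#' @param params [match_params()] thresholds.
#' @param filters [filter_params()] applied to both inputs; comp records
#'   failing filters are counted in `filtered` and excluded from `call_cnt`.
#' @param chunksize Chunking distance; defaults to
#'   `max(1000, refdist + 1)`. `Inf` compares everything per contig in a
#'   single matrix.
#' @param base_sample,comp_sample Samples used for genotype comparison and
#'   concordance (first sample of each input by default).
#' @param outdir Optional directory; when given, writes `tp-base.vcf`,
#'   `tp-comp.vcf`, `fp.vcf`, `fn.vcf` and `summary.json`.
#' @return An `sv_bench` object: `summary` plus the classified record sets
#'   (`tp_base`, `tp_comp`, `fp`, `fn`, `filtered`) and the emitted match
#'   `pairs`.
#' @export
sv_bench <- function(base, comp, reference = NULL, params = match_params(),
                     filters = filter_params(), chunksize = NULL,
                     base_sample = NULL, comp_sample = NULL, outdir = NULL) {
  if (is.character(base)) base <- read_sv_vcf(base, source = "base")
  if (is.character(comp)) comp <- read_sv_vcf(comp, source = "comp")
  base$source <- "base"
  comp$source <- "comp"
  if (params$pctseq > 0) {
    if (is.null(reference))
      stopf("a reference is required when pctseq > 0; pass pctseq = 0 to compare without sequences")
    reference <- read_reference(reference)
  }
  if (is.null(chunksize)) chunksize <- default_chunksize(params$refdist)
  if (is.null(base_sample) && length(attr(base, "samples")))
    base_sample <- attr(base, "samples")[1]
  if (is.null(comp_sample) && length(attr(comp, "samples")))
    comp_sample <- attr(comp, "samples")[1]

  stream <- zip_variants(base, comp)
  ck <- chunk_stream(stream, chunksize = chunksize, filters = filters)
  n_base_kept <- sum(vapply(ck$chunks, function(c) sum(c$source == "base"), 0L))
  if (n_base_kept == 0)
    stopf("no baseline records remain after filtering; recall is undefined")

  assign_fun <- if (params$multimatch) assign_multi else assign_single_best
  base_class <- character(0)
  comp_class <- character(0)
  all_pairs <- list()
  for (chunk in ck$chunks) {
    b <- chunk[chunk$source == "base", , drop = FALSE]
    c_ <- chunk[chunk$source == "comp", , drop = FALSE]
    attr(b, "samples") <- attr(base, "samples")
    attr(c_, "samples") <- attr(comp, "samples")
    pairs <- build_match_matrix(b, c_, params, reference,
                                sample_a = base_sample,
                                sample_b = comp_sample)
    res <- assign_fun(pairs, b$id, c_$id)
    base_class <- c(base_class, res$base_class)
    comp_class <- c(comp_class, res$comp_class)
    if (nrow(res$pairs)) all_pairs[[length(all_pairs) + 1L]] <- res$pairs
  }
  pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else empty_match_table()
  rownames(pairs) <- NULL

  kept <- do.call(bind_records, ck$chunks)
  base_kept <- kept[kept$source == "base", , drop = FALSE]
  comp_kept <- kept[kept$source == "comp", , drop = FALSE]
  subset_cls <- function(recs, cls, label) {
    out <- recs[cls[recs$id] == label, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("sv_records", "data.frame")
    out
  }
  tp_pairs <- pairs[which(pairs$state), , drop = FALSE]
  res <- list(
    tp_base = annotate_matches(subset_cls(base_kept, base_class, "TP"),
                               tp_pairs, "base_id", "comp_id"),
    tp_comp = annotate_matches(subset_cls(comp_kept, comp_class, "TP"),
                               tp_pairs, "comp_id", "base_id"),
    fn = subset_cls(base_kept, base_class, "FN"),
    fp = subset_cls(comp_kept, comp_class, "FP"),
    filtered = ck$filtered,
    pairs = pairs
  )
  gt_total <- sum(!is.na(tp_pairs$gt_match))
  gt_matches <- sum(tp_pairs$gt_match, na.rm = TRUE)
  res$summary <- bench_summary(
    tp_base = nrow(res$tp_base), tp_comp = nrow(res$tp_comp),
    fp = nrow(res$fp), fn = nrow(res$fn), filtered = nrow(ck$filtered),
    gt_matches = gt_matches, gt_total = gt_total
  )
  class(res) <- "sv_bench"
  if (!is.null(outdir)) write_bench(res, outdir, reference)
  res
}

# Attach per-pair metrics as INFO tags on matched records.
annotate_matches <- function(recs, tp_pairs, own_col, other_col) {
  if (!nrow(recs) || !nrow(tp_pairs)) return(recs)
  ix <- match(recs$id, tp_pairs[[own_col]])
  for (i in seq_len(nrow(recs))) {
    j <- ix[i]
    if (is.na(j)) next
    p <- tp_pairs[j, ]
    info <- list(
      TruScore = p$truscore,
      PctSizeSimilarity = p$sizesim,
      PctRecOverlap = p$recovl,
      StartDistance = p$start_distance,
      EndDistance = p$end_distance,
      MatchId = p[[other_col]]
    )
    if (!is.na(p$seqsim)) info$PctSeqSimilarity <- p$seqsim
    if (isTRUE(p$gt_match)) info$GTMatch <- TRUE
    recs$info[[i]] <- info
  }
  recs
}

write_bench <- function(res, outdir, reference = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_sv_vcf(res$tp_base, file.path(outdir, "tp-base.vcf"), reference, sort = TRUE)
  write_sv_vcf(res$tp_comp, file.path(outdir, "tp-comp.vcf"), reference, sort = TRUE)
  write_sv_vcf(res$fp, file.path(outdir, "fp.vcf"), reference, sort = TRUE)
  write_sv_vcf(res$fn, file.path(outdir, "fn.vcf"), reference, sort = TRUE)
  jsonlite::write_json(unclass(res$summary), file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(outdir)
}

#' @export
print.sv_bench <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' @export
summary.sv_bench <- function(object, ...) object$summary
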