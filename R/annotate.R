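# Interval annotations (neighbor counts, breakpoint overlap) and the
# tandem-repeat redundant/missing merge audit. The audit consumes motif /
# copy-number annotations produced upstream (e.g. by a TRF-style annotator);
# `read_tr_annotations()` is the plug-in point for such a sidecar.

#' Count neighboring records and assign neighborhood ids
#'
#' For each record, how many other records lie within `distance` bp
#' (measured between closest span edges), plus a shared identifier for every
#' transitive proximity group.
#'
#' @param records A sorted `sv_records` table.
#' @param distance Neighborhood distance in bp.
#' @return `records` with integer columns `num_neighbors` and `neigh_id`.
#' @export
num_neighbors <- function(records, distance = 1000) {
  n <- nrow(records)
  if (!n) {
    records$num_neighbors <- integer(0)
    records$neigh_id <- integer(0)
    return(records)
  }
  gr <- GenomicRanges::GRanges(
    records$contig,
    IRanges::IRanges(start = records$start + 1L, end = pmax(records$end, records$start + 1L)))
  hits <- GenomicRanges::findOverlaps(gr, gr, maxgap = distance)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  counts <- tabulate(S4Vectors::queryHits(hits), nbins = n)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = distance + 1L)
  memb <- GenomicRanges::findOverlaps(gr, merged, select = "first")
  records$num_neighbors <- counts
  records$neigh_id <- as.integer(memb)
  for (i in seq_len(n))
    records$info[[i]] <- c(records$info[[i]],
                           list(NumNeighbors = counts[i], NeighId = memb[i]))
  records
}

#' Intersect variant breakpoints with annotation intervals
#'
#' Builds an interval tree over the annotation ranges and reports, per
#' record, every interval hit at the start breakpoint, hit at the end
#' breakpoint, containing the variant, or completely overlapped by it.
#'
#' @param records An `sv_records` table.
#' @param intervals A `GRanges` (e.g. from [read_bed()]); unnamed intervals
#'   are labeled by index.
#' @return A data.frame with one row per (record, interval) hit: `id`,
#'   `interval`, `relation` (one of `"contained_within"`,
#'   `"completely_overlaps"`, `"start_bnd"`, `"end_bnd"`).
#' @export
breakpoint_overlap <- function(records, intervals) {
  if (is.null(names(intervals)) || any(is.na(names(intervals))))
    names(intervals) <- as.character(seq_along(intervals))
  n <- nrow(records)
  out <- list()
  gr <- GenomicRanges::GRanges(
    records$contig,
    IRanges::IRanges(start = records$start + 1L, end = pmax(records$end, records$start + 1L)))
  hits <- GenomicRanges::findOverlaps(gr, intervals)
  for (k in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[k]
    j <- S4Vectors::subjectHits(hits)[k]
    vs <- records$start[i] + 1L # 1-based
    ve <- max(records$end[i], records$start[i] + 1L)
    as <- GenomicRanges::start(intervals)[j]
    ae <- GenomicRanges::end(intervals)[j]
    relation <- if (records$svtype[i] == "INS") "start_bnd"
    else if (vs >= as && ve <= ae) "contained_within"
    else if (vs <= as && ve >= ae) "completely_overlaps"
    else if (vs >= as && vs <= ae) "start_bnd"
    else "end_bnd"
    out[[length(out) + 1L]] <- data.frame(
      id = records$id[i], interval = names(intervals)[j],
      relation = relation, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(id = character(0), interval = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read tandem-repeat annotations from a 5-column TSV
#'
#' Columns: contig, start (0-based), locus_id, motif, copy_diff (signed
#' motif copies gained/lost). This is the sidecar interface where a
#' TRF-style annotator would plug in.
#'
#' @param path Path to the TSV (with or without a header line).
#' @return A data.frame with those five columns.
#' @export
read_tr_annotations <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("locus_id", first)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  colnames(df) <- c("contig", "start", "locus_id", "motif", "copy_diff")[seq_len(ncol(df))]
  df
}

#' Label tandem-repeat alleles of one locus as unique or redundant
#'
#' Within each (motif, copy_diff) group one allele is unique and the rest
#' are redundant representations of the same expansion/contraction.
#'
#' @param annotations Data.frame with columns `locus_id`, `motif`,
#'   `copy_diff` (one row per allele of a single locus).
#' @return The input with a `label` column (`"unique"`/`"redundant"`) plus
#'   attributes `unique_count` and `redundant_count`.
#' @export
classify_tr_alleles <- function(annotations) {
  stopifnot(length(unique(annotations$locus_id)) <= 1)
  key <- paste(annotations$motif, annotations$copy_diff, sep = "@")
  annotations$label <- ifelse(duplicated(key), "redundant", "unique")
  attr(annotations, "unique_count") <- sum(annotations$label == "unique")
  attr(annotations, "redundant_count") <- sum(annotations$label == "redundant")
  annotations
}

#' Audit one locus of a merge against the all-representations baseline
#'
#' `missing` counts baseline (motif, copy_diff) keys with no representative
#' left in the merged locus (over-merging); `redundant` counts merged
#' alleles that share a key with another merged allele (under-merging).
#'
#' @param baseline_locus,merged_locus Annotation data.frames (columns
#'   `locus_id`, `motif`, `copy_diff`) for one locus; the baseline holds
#'   every input representation.
#' @return A `tr_locus_audit` list: `locus_id`, `unique_count` (distinct
#'   keys in the merged locus), `redundant_count`, `missing_count`.
#' @export
audit_merge <- function(baseline_locus, merged_locus) {
  lb <- unique(baseline_locus$locus_id)
  lm <- unique(merged_locus$locus_id)
  if (length(lm) && (length(lb) != 1 || !identical(lb, lm)))
    stopf("locus mismatch: baseline '%s' vs merged '%s'",
          paste(lb, collapse = ","), paste(lm, collapse = ","))
  bkey <- unique(paste(baseline_locus$motif, baseline_locus$copy_diff, sep = "@"))
  mkey <- paste(merged_locus$motif, merged_locus$copy_diff, sep = "@")
  structure(list(
    locus_id = lb,
    unique_count = length(unique(mkey)),
    redundant_count = length(mkey) - length(unique(mkey)),
    missing_count = sum(!bkey %in% mkey)
  ), class = "tr_locus_audit")
}

#' @export
print.tr_locus_audit <- function(x, ...) {
  cat(sprintf("<tr_locus_audit> locus %s: unique %d, redundant %d, missing %d\n",
              x$locus_id, x$unique_count, x$redundant_count, x$missing_count))
  invisible(x)
}

#' Audit several merges, dropping uninformative loci
#'
#' Applies [audit_merge()] per locus and merge; loci whose
#' (missing, redundant) outcome is identical across every compared merge are
#' excluded from the summary, since differences in merging strategy had no
#' effect there.
#'
#' @param baseline Annotation data.frame over all loci (the
#'   all-representations merge).
#' @param merges Named list of annotation data.frames, one per merge.
#' @return A data.frame with one row per retained (locus, merge):
#'   `locus_id`, `merge`, `unique_count`, `redundant_count`,
#'   `missing_count`.
#' @export
audit_cohort <- function(baseline, merges) {
  loci <- unique(baseline$locus_id)
  rows <- list()
  for (loc in loci) {
    base_l <- baseline[baseline$locus_id == loc, , drop = FALSE]
    audits <- lapply(merges, function(m)
      audit_merge(base_l, m[m$locus_id == loc, , drop = FALSE]))
    sig <- vapply(audits, function(a)
      paste(a$missing_count, a$redundant_count), "")
    if (length(unique(sig)) == 1) next # identical across merges: excluded
    for (nm in names(audits)) {
      a <- audits[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = loc, merge = nm, unique_count = a$unique_count,
        redundant_count = a$redundant_count, missing_count = a$missing_count,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(locus_id = character(0), merge = character(0),
                      unique_count = integer(0), redundant_count = integer(0),
                      missing_count = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
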