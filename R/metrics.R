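# Pairwise SV similarity metrics. Four gates decide whether a pair of calls
# can match: SV type, reference distance, reciprocal overlap, size
# similarity, and (for sequence-resolved calls) haplotype sequence
# similarity. The three fractional metrics are averaged into a TruScore in
# [0, 100] used to rank putative matches.

#' Matching thresholds for a pairwise comparison
#'
#' Defaults are the benchmarking thresholds (70% sequence and size
#' similarity, 500 bp reference distance, SV-type matching, 0% reciprocal
#' overlap). [collapse_match_params()] gives the stricter merging defaults.
#'
#' @param refdist Maximum positional wobble in bp between the two spans.
#' @param pctseq Minimum haplotype sequence similarity in `[0,1]`; `0`
#'   disables sequence comparison (for non-sequence-resolved callsets).
#' @param pctsize Minimum size similarity in `[0,1]`.
#' @param pctovl Minimum reciprocal overlap in `[0,1]`.
#' @param typematch Require identical SV types.
#' @param gtmatch Require identical (phase-insensitive) genotypes of the
#'   designated samples.
#' @param multimatch Allow a record to participate in more than one match.
#' @param seqsim_symmetric Use the alternative normalization
#'   `1 - 2*ed/totlen` instead of the canonical `1 - ed/totlen` (see the
#'   methods vignette); off by default.
#' @return A `match_params` list.
#' @export
match_params <- function(refdist = 500, pctseq = 0.7, pctsize = 0.7,
                         pctovl = 0, typematch = TRUE, gtmatch = FALSE,
                         multimatch = FALSE, seqsim_symmetric = FALSE) {
  stopifnot(refdist >= 0,
            pctseq >= 0, pctseq <= 1, pctsize >= 0, pctsize <= 1,
            pctovl >= 0, pctovl <= 1)
  structure(list(refdist = refdist, pctseq = pctseq, pctsize = pctsize,
                 pctovl = pctovl, typematch = typematch, gtmatch = gtmatch,
                 multimatch = multimatch, seqsim_symmetric = seqsim_symmetric),
            class = "match_params")
}

#' Default matching thresholds for collapse (95%/95%/500 bp)
#' @inheritParams match_params
#' @param ... Passed on to [match_params()].
#' @return A `match_params` list.
#' @export
collapse_match_params <- function(refdist = 500, pctseq = 0.95,
                                  pctsize = 0.95, pctovl = 0, ...) {
  match_params(refdist = refdist, pctseq = pctseq, pctsize = pctsize,
               pctovl = pctovl, ...)
}

#' Reference-distance gate
#'
#' Two spans are comparable when
#' `max(S1 - refdist, S2) < min(E1 + refdist, E2)` (strict, evaluated on the
#' internal 0-based half-open coordinates; an insertion's span is its anchor
#' base). Records on different contigs are never comparable.
#'
#' @param a,b Single-row `sv_records`.
#' @param refdist Reference distance in bp.
#' @return Logical.
#' @export
reference_distance_ok <- function(a, b, refdist) {
  if (a$contig != b$contig) return(FALSE)
  max(a$start - refdist, b$start) < min(a$end + refdist, b$end)
}

# Span used for overlap computation: insertions are expanded by half their
# length upstream and downstream (they have no physical reference span).
overlap_span <- function(rec) {
  if (rec$svtype == "INS") {
    h <- rec$svlen %/% 2
    c(rec$start - h, rec$end + h)
  } else {
    c(rec$start, rec$end)
  }
}

#' Reciprocal overlap of two spans
#'
#' Overlapping bases divided by the larger of the two spans; 0 when
#' disjoint. Insertion spans are first expanded by half the insertion's
#' length upstream and downstream.
#'
#' @param a,b Single-row `sv_records`.
#' @return Fraction in `[0,1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$contig != b$contig) return(0)
  sa <- overlap_span(a)
  sb <- overlap_span(b)
  os <- max(sa[1], sb[1])
  oe <- min(sa[2], sb[2])
  if (os >= oe) return(0)
  (oe - os) / max(sa[2] - sa[1], sb[2] - sb[1])
}

#' Size similarity of two SVs
#'
#' Minimum SV length over maximum SV length.
#' @param a,b Single-row `sv_records` (or bare lengths via `a$svlen`).
#' @return Fraction in `(0,1]`.
#' @export
size_similarity <- function(a, b) {
  min(a$svlen, b$svlen) / max(a$svlen, b$svlen)
}

#' Construct the two local haplotypes for sequence comparison
#'
#' Over the shared context `[min(S1,S2), max(E1,E2))` each variant's allele
#' is substituted over its own span:
#' `H1 = ref[start:S1] + A1 + ref[E1:end]` and symmetrically for `H2`.
#'
#' @param a,b Single-row sequence-resolved `sv_records` on one contig.
#' @param reference A `DNAStringSet` (or FASTA path) holding the contig.
#' @return Character vector `c(H1, H2)`.
#' @export
build_haplotypes <- function(a, b, reference) {
  reference <- read_reference(reference)
  if (a$contig != b$contig)
    stopf("records %s and %s are on different contigs", a$id, b$id)
  start <- min(a$start, b$start)
  end <- max(a$end, b$end)
  h <- function(r) {
    paste0(ref_slice(reference, r$contig, start, r$start),
           applied_allele(r),
           ref_slice(reference, r$contig, r$end, end))
  }
  c(h(a), h(b))
}

#' Haplotype sequence similarity
#'
#' `1 - edit_distance(H1, H2) / (|H1| + |H2|)`, clamped to `[0,1]`;
#' identical (including empty) haplotypes score 1. The edit distance is the
#' Levenshtein distance. With `symmetric = TRUE` the alternative
#' normalization `1 - 2*ed/totlen` is used instead.
#'
#' @param a,b Single-row sequence-resolved `sv_records`.
#' @param reference A `DNAStringSet` or FASTA path.
#' @param symmetric Use the alternative normalization (default `FALSE`).
#' @return Fraction in `[0,1]`.
#' @export
sequence_similarity <- function(a, b, reference, symmetric = FALSE) {
  h <- build_haplotypes(a, b, reference)
  totlen <- nchar(h[1]) + nchar(h[2])
  if (totlen == 0) return(1)
  ed <- utils::adist(h[1], h[2])[1, 1]
  s <- if (symmetric) 1 - 2 * ed / totlen else 1 - ed / totlen
  min(1, max(0, s))
}

#' Build one putative match between a pair of records
#'
#' Evaluates all enabled gates and records the measured metrics, the signed
#' breakpoint distances (base minus comp), the TruScore, and the pass/fail
#' state. Sequence similarity is skipped (treated as passing and excluded
#' from the TruScore mean) when `params$pctseq == 0`.
#'
#' @param a,b Single-row `sv_records` (a = base, b = comp).
#' @param params A [match_params()] object.
#' @param reference A `DNAStringSet` or FASTA path; required when
#'   `params$pctseq > 0`.
#' @param sample_a,sample_b Sample names used for genotype comparison; when
#'   `NULL` the first sample of each record's callset is used if present.
#' @return A one-row data.frame (class `sv_match`) with columns `base_id`,
#'   `comp_id`, `seqsim`, `sizesim`, `recovl`, `start_distance`,
#'   `end_distance`, `type_match`, `gt_match`, `truscore`, `state`.
#' @export
build_match <- function(a, b, params = match_params(), reference = NULL,
                        sample_a = NULL, sample_b = NULL) {
  out <- build_match_matrix(a, b, params, reference,
                            sample_a = sample_a, sample_b = sample_b)
  class(out) <- c("sv_match", "data.frame")
  out
}

gt_of <- function(rec, sample) {
  fmt <- rec$fmt[[1]]
  if (!length(fmt)) return(NA_character_)
  if (is.null(sample)) sample <- names(fmt)[1]
  record_gt(fmt, sample)
}

# Phase-insensitive genotype key ("0/1" and "1|0" collapse to "0,1").
gt_key <- function(recs, sample) {
  vapply(recs$fmt, function(f) {
    if (!length(f)) return(NA_character_)
    s <- if (is.null(sample)) names(f)[1] else sample
    g <- record_gt(f, s)
    if (is.na(g)) return(NA_character_)
    paste(gt_sorted(g), collapse = ",")
  }, "")
}

#' Build the full match matrix between two record sets
#'
#' One putative match per (base, comp) pair, raveled into a long data.frame
#' with the same columns as [build_match()]. Metric gates are evaluated
#' vectorized; the haplotype comparison runs only for pairs that pass the
#' reference-distance gate (positionally incomparable pairs can never be
#' reported as matches).
#'
#' @param base,comp `sv_records` tables (members of one chunk).
#' @inheritParams build_match
#' @return A data.frame of putative matches (possibly 0-row).
#' @export
build_match_matrix <- function(base, comp, params = match_params(),
                               reference = NULL, sample_a = NULL,
                               sample_b = NULL) {
  nb <- nrow(base)
  nc <- nrow(comp)
  if (!nb || !nc) return(empty_match_table())
  i <- rep(seq_len(nb), each = nc)
  j <- rep.int(seq_len(nc), nb)
  n <- length(i)
  s1 <- base$start[i]; e1 <- base$end[i]; l1 <- base$svlen[i]
  s2 <- comp$start[j]; e2 <- comp$end[j]; l2 <- comp$svlen[j]
  same_ct <- base$contig[i] == comp$contig[j]
  dist_ok <- same_ct &
    pmax(s1 - params$refdist, s2) < pmin(e1 + params$refdist, e2)
  # reciprocal overlap with INS span expansion
  x1 <- ifelse(base$svtype[i] == "INS", l1 %/% 2L, 0L)
  x2 <- ifelse(comp$svtype[j] == "INS", l2 %/% 2L, 0L)
  os <- pmax(s1 - x1, s2 - x2)
  oe <- pmin(e1 + x1, e2 + x2)
  recovl <- ifelse(same_ct & os < oe,
                   (oe - os) / pmax(e1 + x1 - (s1 - x1), e2 + x2 - (s2 - x2)),
                   0)
  sizesim <- pmin(l1, l2) / pmax(l1, l2)
  seqsim <- rep(NA_real_, n)
  if (params$pctseq > 0) {
    for (k in which(dist_ok)) {
      seqsim[k] <- sequence_similarity(base[i[k], ], comp[j[k], ], reference,
                                       symmetric = params$seqsim_symmetric)
    }
  }
  ka <- gt_key(base, sample_a)[i]
  kb <- gt_key(comp, sample_b)[j]
  gt_match <- ifelse(is.na(ka) | is.na(kb), NA, ka == kb)
  type_match <- base$svtype[i] == comp$svtype[j]

  use_seq <- params$pctseq > 0 & !is.na(seqsim)
  truscore <- ifelse(use_seq, (recovl + sizesim + seqsim) / 3,
                     (recovl + sizesim) / 2) * 100
  state <- (!params$typematch | type_match) &
    dist_ok &
    recovl >= params$pctovl &
    sizesim >= params$pctsize &
    (params$pctseq <= 0 | (!is.na(seqsim) & seqsim >= params$pctseq)) &
    (!params$gtmatch | (!is.na(gt_match) & gt_match))

  data.frame(
    base_id = base$id[i], comp_id = comp$id[j],
    base_start = s1, comp_start = s2,
    seqsim = seqsim, sizesim = sizesim, recovl = recovl,
    start_distance = s1 - s2, end_distance = e1 - e2,
    type_match = type_match, gt_match = gt_match,
    truscore = truscore, state = state,
    stringsAsFactors = FALSE
  )
}

empty_match_table <- function() {
  data.frame(base_id = character(0), comp_id = character(0),
             base_start = integer(0), comp_start = integer(0),
             seqsim = numeric(0), sizesim = numeric(0), recovl = numeric(0),
             start_distance = integer(0), end_distance = integer(0),
             type_match = logical(0), gt_match = logical(0),
             truscore = numeric(0), state = logical(0),
             stringsAsFactors = FALSE)
}
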