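# The variant record model: a data.frame with one row per SV and a per-sample
# FORMAT list-column. Internal coordinates are 0-based half-open:
#   * DEL: `start` is the first deleted base, `end = start + svlen`, and the
#     applied allele over [start, end) is the empty string.
#   * INS: `start` is the VCF anchor base (POS - 1), `end = start + 1`, and the
#     applied allele over that one-base span is the full ALT (anchor +
#     insertion), so substituting it reproduces the VCF edit exactly.
#   * Other sequence-resolved records: `start = POS - 1`,
#     `end = start + nchar(REF)`, applied allele is the ALT string.
# VCF 1-based POS is retained in `pos` for round-trip output.

sv_svtypes <- c("DEL", "INS", "INV", "DUP", "OTHER", "BND")

record_columns <- c(
  "id", "source", "contig", "pos", "start", "end", "ref", "alt",
  "svtype", "svlen", "qual", "filter", "fmt", "info"
)

#' Construct a table of SV records
#'
#' Builds the package's internal variant table from parallel vectors. This is
#' the in-memory equivalent of reading a VCF with [read_sv_vcf()]: coordinates
#' are normalized to the internal 0-based half-open convention and SVTYPE /
#' SVLEN are inferred when not supplied.
#'
#' @param contig Chromosome names.
#' @param pos 1-based VCF positions (the anchor base for anchored alleles).
#' @param ref,alt REF / ALT allele strings (one ALT per record; symbolic
#'   tokens such as `<DEL>` are allowed).
#' @param id Record identifiers; autogenerated when `NULL`.
#' @param qual Numeric QUAL (NA for missing).
#' @param filter FILTER strings ("." or "PASS" when unfiltered).
#' @param svtype,svlen Optional explicit SVTYPE / SVLEN (as from INFO); when
#'   `NULL` they are inferred from the alleles.
#' @param end_info Optional 1-based inclusive END (INFO) for symbolic alleles.
#' @param gt Optional genotypes: a character vector (single sample) or a list
#'   of named character vectors (sample -> GT string) per record.
#' @param samples Sample names; defaults to names found in `gt`.
#' @param source Label identifying the originating callset.
#' @return A `data.frame` of class `sv_records`, sorted as given (callers are
#'   responsible for positional sorting), with a `samples` attribute.
#' @export
sv_records <- function(contig, pos, ref, alt, id = NULL, qual = NA_real_,
                       filter = ".", svtype = NULL, svlen = NULL,
                       end_info = NULL, gt = NULL, samples = NULL,
                       source = "input") {
  n <- length(pos)
  contig <- rep_len(as.character(contig), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(as.character(alt), n)
  alt <- ifelse(grepl("^<", alt), alt, toupper(alt))
  if (any(grepl(",", alt, fixed = TRUE)))
    stopf("multiallelic record found (ALT contains ','); split records so each has a single ALT (e.g. 'bcftools norm -m-any') before use")
  id <- if (is.null(id)) sprintf("%s_%d", source, seq_len(n)) else rep_len(as.character(id), n)
  qual <- rep_len(as.numeric(qual), n)
  filter <- rep_len(as.character(filter), n)
  info_svtype <- if (is.null(svtype)) rep(NA_character_, n) else rep_len(as.character(svtype), n)
  info_svlen <- if (is.null(svlen)) rep(NA_integer_, n) else rep_len(suppressWarnings(as.integer(svlen)), n)
  info_end <- if (is.null(end_info)) rep(NA_integer_, n) else rep_len(suppressWarnings(as.integer(end_info)), n)

  type <- character(n)
  size <- integer(n)
  start <- integer(n)
  end <- integer(n)
  for (i in seq_len(n)) {
    type[i] <- infer_svtype(ref[i], alt[i], info_svtype[i])
    size[i] <- if (type[i] == "BND") 1L else
      infer_size(ref[i], alt[i], svlen = info_svlen[i],
                 pos = pos[i], end_info = info_end[i])
    co <- internal_span(pos[i], ref[i], alt[i], type[i], size[i], info_end[i])
    start[i] <- co[1]
    end[i] <- co[2]
  }

  fmt <- normalize_fmt(gt, n)
  if (is.null(samples)) {
    samples <- unique(unlist(lapply(fmt, names)))
    if (is.null(samples)) samples <- character(0)
  }

  out <- data.frame(
    id = id, source = rep_len(source, n), contig = contig,
    pos = as.integer(pos), start = start, end = end, ref = ref, alt = alt,
    svtype = type, svlen = size, qual = qual, filter = filter,
    stringsAsFactors = FALSE
  )
  out$fmt <- fmt
  out$info <- rep(list(NULL), n)
  class(out) <- c("sv_records", "data.frame")
  attr(out, "samples") <- samples
  out
}

# Coerce the gt argument into a list of per-sample named lists of FORMAT maps.
normalize_fmt <- function(gt, n) {
  if (is.null(gt)) return(rep(list(list()), n))
  if (is.character(gt)) {
    gt <- rep_len(gt, n)
    return(lapply(gt, function(g) list(SAMPLE = c(GT = g))))
  }
  stopifnot(is.list(gt), length(gt) == n)
  lapply(gt, function(g) {
    if (is.null(g)) return(list())
    lapply(g, canon_fmt_entry)
  })
}

# Canonical per-sample FORMAT entry: a named character vector with a GT key.
canon_fmt_entry <- function(x) {
  if (is.null(x)) return(c(GT = "./."))
  if (is.list(x)) x <- unlist(x)
  x <- as.character(x)
  nm <- names(x)
  if (is.null(nm) || !any(nzchar(nm))) {
    if (length(x) == 1) return(c(GT = x))
    stop("per-sample FORMAT entries must be named (e.g. c(GT = '0/1'))")
  }
  stats::setNames(x, nm)
}

empty_records <- function(samples = character(0)) {
  out <- data.frame(
    id = character(0), source = character(0), contig = character(0),
    pos = integer(0), start = integer(0), end = integer(0),
    ref = character(0), alt = character(0), svtype = character(0),
    svlen = integer(0), qual = numeric(0), filter = character(0),
    stringsAsFactors = FALSE
  )
  out$fmt <- list()
  out$info <- list()
  class(out) <- c("sv_records", "data.frame")
  attr(out, "samples") <- samples
  out
}

#' Infer the SV type of a single allele pair
#'
#' INFO/SVTYPE takes precedence when recognized; otherwise the type is deduced
#' from allele lengths (longer REF = DEL, longer ALT = INS), symbolic ALT
#' tokens map to their token, and breakend notation maps to BND. Anything
#' unparseable returns "OTHER" rather than erroring.
#'
#' @param ref_allele,alt_allele Allele strings.
#' @param info_svtype Optional SVTYPE string from INFO.
#' @return One of `"DEL"`, `"INS"`, `"INV"`, `"DUP"`, `"OTHER"`, `"BND"`.
#' @export
infer_svtype <- function(ref_allele, alt_allele, info_svtype = NULL) {
  if (!is.null(info_svtype) && length(info_svtype) && !is.na(info_svtype)) {
    tok <- toupper(sub(":.*", "", info_svtype))
    if (tok %in% sv_svtypes) return(tok)
  }
  alt <- alt_allele
  if (is.null(alt) || is.na(alt)) return("OTHER")
  if (grepl("[][]", alt) || alt %in% c("<BND>")) return("BND")
  if (grepl("^<.+>$", alt)) {
    tok <- toupper(sub(":.*", "", sub("^<(.+)>$", "\\1", alt)))
    return(if (tok %in% sv_svtypes) tok else "OTHER")
  }
  if (!grepl("^[ACGTN]+$", alt) || is.na(ref_allele) ||
      !grepl("^[ACGTN]+$", toupper(ref_allele))) return("OTHER")
  rl <- nchar(ref_allele)
  al <- nchar(alt)
  if (rl > al) "DEL" else if (al > rl) "INS" else "OTHER"
}

#' Infer the size (bp) of an SV record
#'
#' `|SVLEN|` when provided; otherwise `abs(nchar(alt) - nchar(ref))` for
#' sequence-resolved alleles, or the reference span from END for symbolic
#' alleles. A deletion's size equals its reference span.
#'
#' @param ref,alt Allele strings.
#' @param svlen Optional INFO/SVLEN (sign ignored).
#' @param pos 1-based position (needed with `end_info`).
#' @param end_info Optional 1-based inclusive INFO/END.
#' @return Size in bp (>= 1 for genuine SVs).
#' @export
infer_size <- function(ref, alt, svlen = NA, pos = NA, end_info = NA) {
  if (!is.na(svlen)) return(abs(as.integer(svlen)))
  symbolic <- grepl("^<", alt)
  if (!symbolic) return(abs(nchar(alt) - nchar(ref)))
  if (!is.na(end_info) && !is.na(pos)) return(as.integer(end_info) - as.integer(pos))
  stopf("record at pos %s has a symbolic ALT (%s) but neither SVLEN nor END; size cannot be determined", pos, alt)
}

# Internal 0-based half-open span for a normalized record.
internal_span <- function(pos, ref, alt, svtype, svlen, end_info = NA) {
  p0 <- as.integer(pos) - 1L # 0-based anchor
  symbolic <- grepl("^<", alt)
  if (svtype == "INS" && !symbolic) {
    c(p0, p0 + 1L)
  } else if (svtype == "DEL") {
    if (symbolic) c(p0 + 1L, p0 + 1L + svlen)
    else if (substr(ref, 1, 1) == substr(alt, 1, 1))
      c(p0 + 1L, p0 + 1L + svlen) # anchored: first deleted base onward
    else c(p0, p0 + nchar(ref))
  } else if (symbolic) {
    e <- if (!is.na(end_info)) as.integer(end_info) else p0 + 1L + svlen
    c(p0 + 1L, e)
  } else {
    c(p0, p0 + nchar(ref))
  }
}

# The sequence substituted over [start, end) when applying the record to the
# reference. Errors on symbolic alleles (no sequence to apply).
applied_allele <- function(rec) {
  if (grepl("^<", rec$alt) || rec$svtype == "BND")
    stopf("record %s has a symbolic or breakend ALT; sequence comparison is impossible (set pctseq = 0)", rec$id)
  switch(rec$svtype,
    DEL = if (substr(rec$ref, 1, 1) == substr(rec$alt, 1, 1)) "" else rec$alt,
    rec$alt
  )
}

#' @export
print.sv_records <- function(x, ...) {
  cat(sprintf("<sv_records> %d record(s), %d sample(s)\n",
              nrow(x), length(attr(x, "samples"))))
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x)[, c("id", "contig", "pos", "svtype",
                                             "svlen", "filter", "source")], 10)
    print(show, row.names = FALSE)
    if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  }
  invisible(x)
}

# rbind that preserves the sv_records class and unions sample sets.
bind_records <- function(...) {
  parts <- Filter(function(p) !is.null(p), list(...))
  parts <- Filter(nrow, parts)
  if (!length(parts)) return(empty_records())
  samples <- unique(unlist(lapply(parts, attr, "samples")))
  out <- do.call(rbind, lapply(parts, function(p) { class(p) <- "data.frame"; p }))
  class(out) <- c("sv_records", "data.frame")
  attr(out, "samples") <- samples %||% character(0)
  rownames(out) <- NULL
  out
}

sort_records <- function(records) {
  if (!nrow(records)) return(records)
  o <- order(records$contig, records$start, method = "radix")
  out <- records[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- attr(records, "samples")
  class(out) <- c("sv_records", "data.frame")
  out
}
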