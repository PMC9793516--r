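# VCF / FASTA / BED input-output. Parsing goes through vcfR and Biostrings;
# the VCF writer is a small formatter for records the package already holds.

#' Read a sorted VCF into an SV record table
#'
#' Parses a (plain or gzipped) VCF 4.2 file with vcfR, normalizes each record
#' to the internal 0-based half-open convention, and rejects multiallelic
#' records with an instructive error. Breakend (BND) records are parsed but
#' never enter comparison streams.
#'
#' @param path Path to the VCF.
#' @param source Label for the originating callset (defaults to the filename).
#' @return An `sv_records` data.frame (see [sv_records()]).
#' @export
read_sv_vcf <- function(path, source = basename(path)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  samples <- if (ncol(v@gt) > 1) colnames(v@gt)[-1] else character(0)
  if (is.null(fix) || nrow(fix) == 0) return(empty_records(samples))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    bad <- which(grepl(",", alt, fixed = TRUE))[1]
    stopf("%s: multiallelic record at %s:%s; split to one ALT per record (e.g. 'bcftools norm -m-any') before use",
          path, fix[bad, "CHROM"], fix[bad, "POS"])
  }
  info_svtype <- vcfR::extract.info(v, "SVTYPE")
  info_svlen <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))
  info_end <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))

  gt <- NULL
  if (length(samples)) {
    fmt_keys <- strsplit(fix_na(v@gt[, 1]), ":", fixed = TRUE)
    gt <- lapply(seq_len(nrow(fix)), function(i) {
      keys <- fmt_keys[[i]]
      per <- lapply(samples, function(s) {
        vals <- strsplit(fix_na(v@gt[i, s]), ":", fixed = TRUE)[[1]]
        stats::setNames(vals[seq_along(keys)], keys)
      })
      stats::setNames(per, samples)
    })
  }

  recs <- sv_records(
    contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt,
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                sprintf("%s_%d", source, seq_len(nrow(fix))), fix[, "ID"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"]),
    svtype = info_svtype, svlen = info_svlen, end_info = info_end,
    gt = gt, samples = samples, source = source
  )
  recs
}

fix_na <- function(x) ifelse(is.na(x), ".", x)

#' Write an SV record table as a plain-text VCF
#'
#' @param records An `sv_records` table (sorted output is the caller's duty;
#'   use `sort = TRUE` to sort by position first).
#' @param path Output path.
#' @param reference Optional `DNAStringSet` used to emit contig header lines.
#' @param sort Sort records by (contig, start) before writing.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path, reference = NULL, sort = FALSE) {
  if (sort) records <- sort_records(records)
  samples <- attr(records, "samples") %||% character(0)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svmatchr",
    if (!is.null(reference))
      sprintf("##contig=<ID=%s,length=%d>", names(reference),
              Biostrings::width(reference)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of structural variant\">",
    "##INFO=<ID=TruScore,Number=1,Type=Float,Description=\"Mean of match metrics scaled to [0,100]\">",
    "##INFO=<ID=PctSeqSimilarity,Number=1,Type=Float,Description=\"Haplotype sequence similarity of the match\">",
    "##INFO=<ID=PctSizeSimilarity,Number=1,Type=Float,Description=\"Size similarity of the match\">",
    "##INFO=<ID=PctRecOverlap,Number=1,Type=Float,Description=\"Reciprocal overlap of the match\">",
    "##INFO=<ID=StartDistance,Number=1,Type=Integer,Description=\"Signed start breakpoint distance (base - comp)\">",
    "##INFO=<ID=EndDistance,Number=1,Type=Integer,Description=\"Signed end breakpoint distance (base - comp)\">",
    "##INFO=<ID=GTMatch,Number=0,Type=Flag,Description=\"Genotypes of the matched pair agree\">",
    "##INFO=<ID=MatchId,Number=1,Type=String,Description=\"Identifier of the matched/representative record\">",
    "##INFO=<ID=NumNeighbors,Number=1,Type=Integer,Description=\"Records within the neighborhood distance\">",
    "##INFO=<ID=NeighId,Number=1,Type=Integer,Description=\"Transitive proximity group identifier\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    svlen_signed <- if (r$svtype == "DEL") -r$svlen else r$svlen
    info <- c(
      sprintf("SVTYPE=%s", r$svtype),
      if (r$svtype != "BND") sprintf("SVLEN=%d", svlen_signed),
      if (r$svtype == "DEL") sprintf("END=%d", r$end),
      format_info(records$info[[i]])
    )
    fmt <- records$fmt[[i]]
    gcols <- character(0)
    if (length(samples)) {
      keys <- unique(unlist(lapply(fmt, names))) %||% "GT"
      if (!length(keys)) keys <- "GT"
      if (!"GT" %in% keys) keys <- c("GT", keys)
      gcols <- c(paste(keys, collapse = ":"),
                 vapply(samples, function(s) {
                   f <- fmt[[s]]
                   paste(vapply(keys, function(k) {
                     val <- if (is.null(f)) NULL else f[[k]]
                     if (is.null(val) || is.na(val)) {
                       if (k == "GT") "./." else "."
                     } else as.character(val)
                   }, ""), collapse = ":")
                 }, ""))
    }
    paste(c(r$contig, r$pos, r$id, r$ref, r$alt,
            ifelse(is.na(r$qual), ".", format(r$qual)),
            r$filter, paste(info, collapse = ";"), gcols), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

format_info <- function(info) {
  if (is.null(info) || !length(info)) return(character(0))
  vapply(names(info), function(k) {
    v <- info[[k]]
    if (isTRUE(v)) k
    else if (is.numeric(v) && k %in% c("TruScore", "PctSeqSimilarity",
                                       "PctSizeSimilarity", "PctRecOverlap"))
      sprintf("%s=%s", k, formatC(v, format = "f", digits = 4))
    else sprintf("%s=%s", k, as.character(v))
  }, "")
}

#' Read a reference genome from FASTA (or pass a DNAStringSet through)
#' @param reference Path to a FASTA file or a `Biostrings::DNAStringSet`.
#' @return A `DNAStringSet`.
#' @export
read_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) return(reference)
  Biostrings::readDNAStringSet(reference)
}

# Reference slice on internal 0-based half-open coordinates.
ref_slice <- function(reference, contig, start0, end0) {
  if (!contig %in% names(reference))
    stopf("contig '%s' not present in the reference", contig)
  if (end0 <= start0) return("")
  as.character(Biostrings::subseq(reference[[contig]], start0 + 1L, end0))
}

#' Read a BED file (0-based half-open) as region intervals
#' @param path Path to a 3+ column BED file.
#' @return A `GRanges` of the intervals; names come from column 4 when present.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]])
  )
  if (ncol(df) >= 4) names(gr) <- as.character(df[[4]])
  gr
}
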