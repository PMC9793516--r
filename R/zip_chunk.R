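# Streaming architecture: multiple sorted callsets are zipped into one
# position-ordered stream, filtered, and grouped into positionally isolated
# chunks. All downstream comparison happens within a chunk, so with
# chunksize >= refdist no cross-chunk pair can ever satisfy the
# reference-distance gate.

#' Filtering parameters for the chunker
#'
#' @param sizemin,sizemax Size bounds in bp (inclusive). The 50 bp floor is
#'   the conventional SV definition; the ceiling bounds haplotype
#'   construction cost.
#' @param passonly Keep only records whose FILTER is PASS or missing.
#' @param include_regions Optional `GRanges` (e.g. from [read_bed()]);
#'   records whose start lies outside every region are dropped.
#' @param require_present_genotype Optional sample name; records where that
#'   sample's genotype carries no ALT allele are dropped.
#' @return A `filter_params` list.
#' @export
filter_params <- function(sizemin = 50, sizemax = 50000, passonly = FALSE,
                          include_regions = NULL,
                          require_present_genotype = NULL) {
  stopifnot(sizemin > 0, sizemin <= sizemax)
  structure(list(sizemin = sizemin, sizemax = sizemax, passonly = passonly,
                 include_regions = include_regions,
                 require_present_genotype = require_present_genotype),
            class = "filter_params")
}

#' Test which records pass the chunker filters
#'
#' @param records An `sv_records` table.
#' @param filters A [filter_params()] object.
#' @return Logical vector, one element per record.
#' @export
passes_filters <- function(records, filters) {
  if (!nrow(records)) return(logical(0))
  ok <- records$svlen >= filters$sizemin & records$svlen <= filters$sizemax
  ok <- ok & records$svtype != "BND"
  if (filters$passonly)
    ok <- ok & records$filter %in% c("PASS", ".", "")
  if (!is.null(filters$include_regions)) {
    pts <- GenomicRanges::GRanges(
      records$contig, IRanges::IRanges(records$start + 1L, records$start + 1L))
    hit <- IRanges::overlapsAny(pts, filters$include_regions)
    ok <- ok & hit
  }
  if (!is.null(filters$require_present_genotype)) {
    s <- filters$require_present_genotype
    if (!s %in% (attr(records, "samples") %||% character(0)))
      stopf("sample '%s' not present in the input(s)", s)
    present <- vapply(records$fmt, function(f) {
      ac <- gt_alt_count(record_gt(f, s))
      !is.na(ac) && ac > 0
    }, TRUE)
    ok <- ok & present
  }
  ok
}

#' Zip sorted record streams into one position-ordered stream
#'
#' Merges any number of sorted callsets into a single stream ordered by
#' alphanumeric-ascending contig and position, stable for ties (earlier
#' inputs, e.g. base before comp, come first). Each input must already be
#' sorted; an out-of-order record raises an error naming its contig and
#' position.
#'
#' @param ... `sv_records` tables (or a single list of them).
#' @return One merged `sv_records` table with unioned samples.
#' @export
zip_variants <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  for (s in sets) check_sorted(s)
  tagged <- lapply(seq_along(sets), function(k) {
    s <- sets[[k]]
    if (!nrow(s)) return(NULL)
    s$.zip_src <- k
    s
  })
  out <- do.call(bind_records, tagged)
  if (!nrow(out)) return(out)
  o <- order(out$contig, out$start, out$.zip_src, method = "radix")
  out <- out[o, , drop = FALSE]
  out$.zip_src <- NULL
  rownames(out) <- NULL
  class(out) <- c("sv_records", "data.frame")
  attr(out, "samples") <- unique(unlist(lapply(sets, attr, "samples"))) %||% character(0)
  out
}

check_sorted <- function(records) {
  if (nrow(records) < 2) return(invisible(TRUE))
  contig <- records$contig
  # contigs must appear in ascending alphanumeric order, each as one block
  blocks <- rle(contig)$values
  if (length(blocks) > 1) {
    bad <- which(duplicated(blocks) |
                   c(FALSE, blocks[-1] < blocks[-length(blocks)]))
    if (length(bad))
      stopf("input '%s' is not sorted: contig '%s' out of alphanumeric order",
            records$source[1], blocks[bad[1]])
  }
  for (ct in blocks) {
    p <- records$start[contig == ct]
    if (is.unsorted(p)) {
      i <- which(diff(p) < 0)[1]
      stopf("input '%s' is not sorted at %s:%d", records$source[1], ct,
            records$pos[contig == ct][i + 1])
    }
  }
  invisible(TRUE)
}

#' Group a zipped stream into positionally isolated chunks
#'
#' A new chunk begins exactly when the next record's start exceeds the
#' running maximum end of the current chunk plus `chunksize`, or when the
#' contig changes. Records failing `filters` are excluded before grouping and
#' returned separately so callers (e.g. bench) can count them.
#'
#' @param stream A zipped `sv_records` table (see [zip_variants()]).
#' @param chunksize Gap in bp that separates chunks.
#' @param filters Optional [filter_params()].
#' @return A list with `chunks` (list of `sv_records`) and `filtered`
#'   (`sv_records` of excluded records).
#' @export
chunk_stream <- function(stream, chunksize = 1000, filters = NULL) {
  if (!is.null(filters)) {
    keep <- passes_filters(stream, filters)
    filtered <- stream[!keep, , drop = FALSE]
    stream <- stream[keep, , drop = FALSE]
  } else {
    filtered <- stream[0, , drop = FALSE]
  }
  rownames(stream) <- NULL
  samples <- attr(stream, "samples")
  restore <- function(df) {
    rownames(df) <- NULL
    class(df) <- c("sv_records", "data.frame")
    attr(df, "samples") <- samples
    df
  }
  filtered <- restore(filtered)
  if (!nrow(stream)) return(list(chunks = list(), filtered = filtered))
  n <- nrow(stream)
  chunk_id <- integer(n)
  cur <- 1L
  run_max_end <- stream$end[1]
  chunk_id[1] <- cur
  if (n > 1) for (i in 2:n) {
    if (stream$contig[i] != stream$contig[i - 1] ||
        stream$start[i] > run_max_end + chunksize) {
      cur <- cur + 1L
      run_max_end <- stream$end[i]
    } else {
      run_max_end <- max(run_max_end, stream$end[i])
    }
    chunk_id[i] <- cur
  }
  chunks <- lapply(split(seq_len(n), chunk_id),
                   function(ix) restore(stream[ix, , drop = FALSE]))
  names(chunks) <- NULL
  list(chunks = chunks, filtered = filtered)
}

#' Default chunk size for a given reference distance
#'
#' `max(1000, refdist + 1)`, which guarantees that records in different
#' chunks can never pass the reference-distance gate.
#' @param refdist Reference distance in bp.
#' @return Chunk size in bp.
#' @export
default_chunksize <- function(refdist) max(1000, refdist + 1)
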