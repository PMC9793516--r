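# Redundancy-aware merging: NxN matching within chunks, clustering,
# representative selection and genotype consolidation.

#' Can two genotypes of one sample coexist as distinct variants?
#'
#' Used in haplotype-aware (`hap`) collapsing: two calls in the same sample
#' cannot be merged when their genotypes claim overlapping haplotype slots
#' (e.g. a homozygous-ALT call against anything carrying ALT, or two phased
#' hets on the same haplotype). Unphased hets are compatible (they could lie
#' on opposite haplotypes). Missing genotypes are treated as compatible.
#'
#' @param gt_a,gt_b GT strings (e.g. "1/1", "0|1").
#' @return Logical: `TRUE` when the pair may be merged.
#' @export
gt_compatible <- function(gt_a, gt_b) {
  ca <- gt_alt_count(gt_a)
  cb <- gt_alt_count(gt_b)
  if (is.na(ca) || is.na(cb) || ca == 0 || cb == 0) return(TRUE)
  if (ca >= 2 || cb >= 2) return(FALSE) # hom ALT overlaps any ALT carrier
  if (gt_is_phased(gt_a) && gt_is_phased(gt_b)) {
    ha <- which(gt_alleles(gt_a) > 0)
    hb <- which(gt_alleles(gt_b) > 0)
    return(!any(ha %in% hb)) # same phased haplotype slot -> incompatible
  }
  TRUE
}

#' Transitive clustering of passing matches
#'
#' Connected components of the passing-match graph (chain mode): two
#' variants that do not directly match but share an intermediate match land
#' in one cluster.
#'
#' @param ids All record ids of the chunk.
#' @param pass_pairs Two-column data.frame/matrix of passing pair ids.
#' @return Integer cluster membership named by id.
#' @export
chain_clusters <- function(ids, pass_pairs) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (NROW(pass_pairs))
    g <- igraph::add_edges(g, rbind(match(pass_pairs[[1]], ids),
                                    match(pass_pairs[[2]], ids)))
  comp <- igraph::components(g)
  stats::setNames(comp$membership, ids)
}

#' Choose a cluster's representative record
#'
#' `first` keeps the most upstream variant; `maxqual` the highest QUAL (all
#' missing falls back to `first`); `common` the highest ALT-allele count
#' across samples. Ties break by (start, input order).
#'
#' @param cluster `sv_records` rows of one cluster.
#' @param keep `"first"`, `"maxqual"` or `"common"`.
#' @return The index (within `cluster`) of the representative.
#' @export
choose_representative <- function(cluster, keep = c("first", "maxqual", "common")) {
  keep <- match.arg(keep)
  n <- nrow(cluster)
  tie <- order(cluster$start, seq_len(n))
  if (keep == "first") return(tie[1])
  if (keep == "maxqual") {
    if (all(is.na(cluster$qual))) return(tie[1])
    q <- ifelse(is.na(cluster$qual), -Inf, cluster$qual)
    return(order(-q, cluster$start, seq_len(n))[1])
  }
  ac <- vapply(cluster$fmt, function(f) {
    sum(vapply(f, function(x) {
      v <- gt_alt_count(x[["GT"]] %||% NA_character_)
      if (is.na(v)) 0L else v
    }, 0L))
  }, 0L)
  order(-ac, cluster$start, seq_len(n))[1]
}

#' Consolidate a cluster's genotypes onto its representative
#'
#' Per sample, the representative's ALT-allele count becomes
#' `min(2, sum of members' ALT counts)` (diploid saturation); phase is
#' dropped when the genotype is modified. Non-GT per-sample fields are taken
#' from the member that contributed the call for that sample.
#'
#' @param cluster `sv_records` rows of one cluster.
#' @param rep_idx Index of the representative within `cluster`.
#' @param samples Sample names of the callset.
#' @return A per-sample FORMAT map for the representative, with attribute
#'   `"saturated"` counting genotypes capped at 2.
#' @export
consolidate_genotypes <- function(cluster, rep_idx = 1,
                                  samples = names(cluster$fmt[[rep_idx]])) {
  saturated <- 0L
  out <- lapply(samples, function(s) {
    gts <- vapply(cluster$fmt, function(f) record_gt(f, s), "")
    counts <- vapply(gts, gt_alt_count, 0L)
    if (all(is.na(counts))) {
      f <- cluster$fmt[[rep_idx]][[s]]
      return(f %||% c(GT = "./."))
    }
    total <- sum(counts, na.rm = TRUE)
    if (total > 2) saturated <<- saturated + 1L
    total <- min(2L, total)
    # carry non-GT fields from the member that contributed this sample's call
    donor <- which(!is.na(counts) & counts > 0)[1]
    if (is.na(donor)) donor <- rep_idx
    f <- cluster$fmt[[donor]][[s]] %||% c(GT = "./.")
    f[["GT"]] <- c("0/0", "0/1", "1/1")[total + 1L]
    f
  })
  out <- stats::setNames(out, samples)
  attr(out, "saturated") <- saturated
  out
}

#' Collapse redundant SV representations
#'
#' Builds the NxN match matrix within each chunk, clusters matching records
#' (transitively when `chain = TRUE`, otherwise by a position-ordered seed
#' scan in which each unconsumed record gathers the later records that
#' directly match it), selects a representative per cluster and consolidates
#' genotypes onto it. Kept and removed records partition the filtered input;
#' removed records carry a `MatchId` INFO tag naming their representative.
#'
#' @param vcfs A path / `sv_records` table, or a list of them (multiple
#'   inputs are zipped into one multi-sample stream).
#' @param reference `DNAStringSet` or FASTA path (required when
#'   `params$pctseq > 0`).
#' @param params [match_params()]; defaults to the merging thresholds
#'   [collapse_match_params()] (95%/95%/500 bp).
#' @param hap Haplotype-aware mode: requires single-sample input; pairs with
#'   incompatible genotypes (see [gt_compatible()]) never match.
#' @param chain Transitive clustering via shared intermediate matches.
#' @param keep Representative selection: `"first"`, `"maxqual"`, `"common"`.
#' @param filters [filter_params()]; collapse defaults to no size floor so
#'   that all input records are considered.
#' @param chunksize Chunking distance (default `max(1000, refdist + 1)`).
#' @param outdir Optional directory for `kept.vcf` / `removed.vcf`.
#' @return An `sv_collapse` object: `kept`, `removed`, `clusters` (id ->
#'   representative id map), `n_saturated`, `filtered`.
#' @export
sv_collapse <- function(vcfs, reference = NULL,
                        params = collapse_match_params(),
                        hap = FALSE, chain = FALSE,
                        keep = c("first", "maxqual", "common"),
                        filters = filter_params(sizemin = 1),
                        chunksize = NULL, outdir = NULL) {
  keep <- match.arg(keep)
  if (is.character(vcfs) || is.data.frame(vcfs)) vcfs <- list(vcfs)
  sets <- lapply(seq_along(vcfs), function(k) {
    v <- vcfs[[k]]
    if (is.character(v)) v <- read_sv_vcf(v, source = sprintf("in%d", k))
    v
  })
  stream <- zip_variants(sets)
  samples <- attr(stream, "samples")
  if (hap && length(samples) != 1)
    stopf("hap mode requires a single-sample input (found %d samples)", length(samples))
  if (params$pctseq > 0) {
    if (is.null(reference))
      stopf("a reference is required when pctseq > 0; pass pctseq = 0 to collapse without sequences")
    reference <- read_reference(reference)
  }
  if (is.null(chunksize)) chunksize <- default_chunksize(params$refdist)
  ck <- chunk_stream(stream, chunksize = chunksize, filters = filters)

  kept <- list()
  removed <- list()
  cluster_map <- character(0)
  n_sat <- 0L
  for (chunk in ck$chunks) {
    attr(chunk, "samples") <- samples
    res <- collapse_chunk(chunk, params, reference, hap, chain, keep, samples)
    kept[[length(kept) + 1L]] <- res$kept
    removed[[length(removed) + 1L]] <- res$removed
    cluster_map <- c(cluster_map, res$map)
    n_sat <- n_sat + res$saturated
  }
  kept <- sort_records(do.call(bind_records, kept))
  removed <- do.call(bind_records, removed)
  attr(kept, "samples") <- samples
  attr(removed, "samples") <- samples
  out <- list(kept = kept, removed = removed, clusters = cluster_map,
              n_saturated = n_sat, filtered = ck$filtered)
  class(out) <- "sv_collapse"
  if (n_sat > 0)
    warning(sprintf("%d consolidated genotype(s) saturated at the diploid ALT count of 2", n_sat))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_sv_vcf(kept, file.path(outdir, "kept.vcf"), reference)
    write_sv_vcf(removed, file.path(outdir, "removed.vcf"), reference, sort = TRUE)
  }
  out
}

collapse_chunk <- function(chunk, params, reference, hap, chain, keep, samples) {
  n <- nrow(chunk)
  empty <- chunk[0, , drop = FALSE]
  if (n == 1)
    return(list(kept = chunk, removed = empty,
                map = stats::setNames(chunk$id, chunk$id), saturated = 0L))

  state <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m <- build_match(chunk[i, ], chunk[j, ], params, reference)
      ok <- m$state
      if (ok && hap) {
        ga <- record_gt(chunk$fmt[[i]], samples[1])
        gb <- record_gt(chunk$fmt[[j]], samples[1])
        ok <- gt_compatible(ga, gb)
      }
      state[i, j] <- state[j, i] <- ok
    }
  }

  if (chain) {
    pp <- which(upper.tri(state) & state, arr.ind = TRUE)
    membership <- chain_clusters(chunk$id,
                                 data.frame(a = chunk$id[pp[, 1]],
                                            b = chunk$id[pp[, 2]]))
    groups <- split(seq_len(n), membership[chunk$id])
  } else {
    # position-ordered seed scan: each unconsumed record gathers the later
    # unconsumed records that directly match it
    ord <- order(chunk$start, seq_len(n))
    consumed <- rep(FALSE, n)
    groups <- list()
    for (i in ord) {
      if (consumed[i]) next
      consumed[i] <- TRUE
      members <- i
      for (j in ord) {
        if (consumed[j]) next
        if (state[i, j]) {
          consumed[j] <- TRUE
          members <- c(members, j)
        }
      }
      groups[[length(groups) + 1L]] <- members
    }
  }

  kept <- list()
  removed <- list()
  map <- character(0)
  saturated <- 0L
  for (g in groups) {
    cl <- chunk[g, , drop = FALSE]
    rix <- choose_representative(cl, keep)
    rep_rec <- cl[rix, , drop = FALSE]
    if (nrow(cl) > 1 && length(samples)) {
      fmt <- consolidate_genotypes(cl, rix, samples)
      saturated <- saturated + attr(fmt, "saturated")
      attr(fmt, "saturated") <- NULL
      rep_rec$fmt[[1]] <- fmt
    }
    map <- c(map, stats::setNames(rep(rep_rec$id, nrow(cl)), cl$id))
    others <- cl[-rix, , drop = FALSE]
    if (nrow(others)) {
      for (k in seq_len(nrow(others)))
        others$info[[k]] <- c(others$info[[k]], list(MatchId = rep_rec$id))
    }
    kept[[length(kept) + 1L]] <- rep_rec
    removed[[length(removed) + 1L]] <- others
  }
  list(kept = do.call(bind_records, kept),
       removed = do.call(bind_records, removed),
       map = map, saturated = saturated)
}

#' @export
print.sv_collapse <- function(x, ...) {
  cat(sprintf("<sv_collapse> kept %d, removed %d (filtered %d)\n",
              nrow(x$kept), nrow(x$removed), nrow(x$filtered)))
  invisible(x)
}
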