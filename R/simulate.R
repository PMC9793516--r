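# Deterministic synthetic fixtures: random references with optional planted
# tandem-repeat arrays, implanted truth callsets with genotypes, perturbed
# replicate callsets with a machine-readable ledger, and the worked
# tandem-repeat locus of eight insertion alleles used by the merge audit.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random reference genome
#'
#' Random nucleotide contigs, optionally with planted tandem-repeat arrays
#' (motif repeated `copies` times) overwriting the sequence at recorded
#' positions. Byte-identical for a given seed.
#'
#' @param n_contigs Number of contigs.
#' @param length Length of each contig in bp (>= 10 kb recommended).
#' @param seed Integer seed.
#' @param repeats Optional data.frame with columns `contig` (index or name),
#'   `start` (0-based), `motif`, `copies`.
#' @return A list: `seq` (`DNAStringSet`) and `repeats` (coordinates of the
#'   planted arrays, 0-based half-open).
#' @export
make_reference <- function(n_contigs = 1, length = 1e5, seed = 42,
                           repeats = NULL) {
  with_seed(seed, {
    seqs <- vapply(seq_len(n_contigs), function(i) random_dna(length), "")
    names(seqs) <- sprintf("ctg%d", seq_len(n_contigs))
    planted <- NULL
    if (!is.null(repeats)) {
      planted <- repeats
      planted$contig <- ifelse(grepl("^[0-9]+$", as.character(repeats$contig)),
                               names(seqs)[as.integer(repeats$contig)],
                               as.character(repeats$contig))
      for (i in seq_len(nrow(planted))) {
        arr <- strrep(planted$motif[i], planted$copies[i])
        s <- planted$start[i]
        if (s + nchar(arr) > length)
          stopf("planted repeat %d does not fit on the contig", i)
        ct <- planted$contig[i]
        substr(seqs[ct], s + 1, s + nchar(arr)) <- arr
      }
      planted$end <- planted$start + nchar(planted$motif) * planted$copies
    }
    list(seq = Biostrings::DNAStringSet(seqs), repeats = planted)
  })
}

#' Implant non-overlapping DEL/INS truth SVs into a reference
#'
#' Draws well-separated footprints, builds anchored sequence-resolved
#' records, and assigns random genotypes over `n_samples` samples (every
#' variant is carried by at least one sample).
#'
#' @param reference A `DNAStringSet` or the list returned by
#'   [make_reference()].
#' @param n_del,n_ins Number of deletions / insertions.
#' @param size_range SV sizes drawn uniformly from this range (bp).
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param min_gap Minimum bp between consecutive SV footprints; the default
#'   keeps truth records in separate chunks at default parameters.
#' @param p_hom Probability that a carried genotype is homozygous ALT.
#' @return A sorted `sv_records` truth table (source "truth").
#' @export
implant_svs <- function(reference, n_del = 25, n_ins = 25,
                        size_range = c(50, 1000), n_samples = 1, seed = 42,
                        min_gap = 1500, p_hom = 0.3) {
  if (is.list(reference) && !methods::is(reference, "DNAStringSet"))
    reference <- reference$seq
  with_seed(seed, {
    n <- n_del + n_ins
    contigs <- names(reference)
    widths <- Biostrings::width(reference)
    # spread loci over contigs proportionally to length
    ct_idx <- sample(seq_along(contigs), n, replace = TRUE, prob = widths)
    types_all <- sample(rep(c("DEL", "INS"), times = c(n_del, n_ins)))
    recs <- list()
    for (ci in unique(ct_idx)) {
      k <- sum(ct_idx == ci)
      L <- widths[ci]
      need <- k * (max(size_range) + min_gap)
      slack <- L - 2000 - need
      if (slack < k)
        stopf("cannot place %d SVs of up to %d bp with %d bp gaps on a %d bp contig; use fewer or smaller SVs", k, max(size_range), min_gap, L)
      # ordered anchors with guaranteed gaps
      gaps <- diff(c(0, sort(sample.int(slack, k))))
      anchor <- 1000 + cumsum(gaps + max(size_range) + min_gap) -
        (max(size_range) + min_gap)
      types <- types_all[ct_idx == ci]
      sizes <- sample(seq(size_range[1], size_range[2]), k, replace = TRUE)
      for (j in seq_len(k)) {
        p0 <- anchor[j] # 0-based anchor base
        anchor_base <- ref_slice(reference, contigs[ci], p0, p0 + 1)
        if (types[j] == "DEL") {
          ref_al <- paste0(anchor_base,
                           ref_slice(reference, contigs[ci], p0 + 1, p0 + 1 + sizes[j]))
          alt_al <- anchor_base
        } else {
          ref_al <- anchor_base
          alt_al <- paste0(anchor_base, random_dna(sizes[j]))
        }
        gts <- vapply(seq_len(n_samples), function(s)
          if (stats::runif(1) < p_hom) "1/1" else "0/1", "")
        carrier <- sample(n_samples, 1)
        drop_mask <- stats::runif(n_samples) < 0.3
        drop_mask[carrier] <- FALSE
        gts[drop_mask] <- "0/0"
        recs[[length(recs) + 1L]] <- list(
          contig = contigs[ci], pos = p0 + 1, ref = ref_al, alt = alt_al,
          gt = gts)
      }
    }
    smp <- sprintf("S%02d", seq_len(n_samples))
    truth <- sv_records(
      contig = vapply(recs, `[[`, "", "contig"),
      pos = vapply(recs, `[[`, 0, "pos"),
      ref = vapply(recs, `[[`, "", "ref"),
      alt = vapply(recs, `[[`, "", "alt"),
      qual = round(stats::runif(length(recs), 20, 60), 1),
      filter = "PASS",
      gt = lapply(recs, function(r) stats::setNames(as.list(r$gt), smp)),
      samples = smp, source = "truth"
    )
    truth <- sort_records(truth)
    truth$id <- sprintf("truth_%d", seq_len(nrow(truth)))
    truth
  })
}

#' Perturbation model for replicate callsets
#'
#' Describes how a truth callset is degraded into a comparison callset.
#' Positional shift, size jitter and per-base sequence errors act on
#' insertions; deletions are perturbed positionally only (with the
#' haplotype-similarity formula, any breakpoint perturbation of a deletion
#' in non-repetitive sequence collapses sequence similarity, so there is no
#' "gentle" deletion perturbation to emulate — see the methods vignette).
#'
#' @param pos_shift Length-2 bp range for positional shifts (sign random).
#' @param size_jitter Length-2 fractional range; an insertion's length is
#'   scaled by a factor drawn from `1 + [range]` (extension appends novel
#'   bases, truncation trims the tail).
#' @param seq_error_rate Per-base substitution probability on inserted
#'   sequence.
#' @param drop_rate Probability a truth record is dropped (future FN).
#' @param novel_rate Expected fraction of novel records added (future FP).
#' @param shift_dels Also shift deletions (used for refdist-violation
#'   regimes).
#' @param seq_replace Replace each inserted sequence by a same-length
#'   homopolymer. Random substitutions cannot push the haplotype similarity
#'   of equal-length insertions below ~0.75 under the `1 - ed/totlen`
#'   normalization, so this adversarial low-complexity replacement is the
#'   regime that violates the sequence-similarity gate in isolation.
#' @param seed Integer seed.
#' @return A `perturbation_model` list.
#' @export
perturbation_model <- function(pos_shift = c(0, 0), size_jitter = c(0, 0),
                               seq_error_rate = 0, drop_rate = 0,
                               novel_rate = 0, shift_dels = FALSE,
                               seq_replace = FALSE, seed = 1) {
  stopifnot(seq_error_rate >= 0, seq_error_rate <= 1,
            drop_rate >= 0, drop_rate <= 1, novel_rate >= 0, novel_rate <= 1)
  structure(list(pos_shift = pos_shift, size_jitter = size_jitter,
                 seq_error_rate = seq_error_rate, drop_rate = drop_rate,
                 novel_rate = novel_rate, shift_dels = shift_dels,
                 seq_replace = seq_replace, seed = seed),
            class = "perturbation_model")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0 || !nchar(seq)) return(list(seq = seq, n = 0L))
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  list(seq = paste(bases, collapse = ""), n = length(hit))
}

#' Perturb a truth callset into a comparison callset
#'
#' Applies the [perturbation_model()] per record and returns both the
#' perturbed callset and a ledger describing exactly what was done to each
#' record, so expected bench TP/FP/FN counts are computable rather than
#' guessed.
#'
#' @param truth A truth `sv_records` table (from [implant_svs()]).
#' @param reference `DNAStringSet` or [make_reference()] list.
#' @param model A [perturbation_model()].
#' @return A list: `comp` (sorted `sv_records`, source "comp") and `ledger`
#'   (data.frame with `id`, `action` ("kept"/"dropped"/"novel"), `shift`,
#'   `jitter_frac`, `n_errors`, `new_size`).
#' @export
perturb_callset <- function(truth, reference, model = perturbation_model()) {
  if (is.list(reference) && !methods::is(reference, "DNAStringSet"))
    reference <- reference$seq
  with_seed(model$seed, {
    rows <- list()
    ledger <- list()
    for (i in seq_len(nrow(truth))) {
      r <- truth[i, ]
      if (stats::runif(1) < model$drop_rate) {
        ledger[[length(ledger) + 1L]] <- data.frame(
          id = r$id, action = "dropped", shift = 0L, jitter_frac = 0,
          n_errors = 0L, new_size = r$svlen, stringsAsFactors = FALSE)
        next
      }
      shift <- 0L
      jit <- 0
      nerr <- 0L
      pos <- r$pos
      ref_al <- r$ref
      alt_al <- r$alt
      shiftable <- r$svtype == "INS" || model$shift_dels
      if (shiftable && max(model$pos_shift) > 0) {
        mag <- if (model$pos_shift[1] == model$pos_shift[2]) model$pos_shift[1]
        else sample(seq(model$pos_shift[1], model$pos_shift[2]), 1)
        shift <- mag * sample(c(-1L, 1L), 1)
        pos <- max(2L, pos + shift)
        shift <- pos - r$pos
        anchor <- ref_slice(reference, r$contig, pos - 1, pos)
        if (r$svtype == "INS") {
          alt_al <- paste0(anchor, substring(r$alt, 2))
          ref_al <- anchor
        } else {
          ref_al <- paste0(anchor,
                           ref_slice(reference, r$contig, pos, pos + r$svlen))
          alt_al <- anchor
        }
      }
      if (r$svtype == "INS") {
        ins <- substring(alt_al, 2)
        if (max(abs(model$size_jitter)) > 0) {
          jit <- stats::runif(1, model$size_jitter[1], model$size_jitter[2])
          new_len <- max(1L, as.integer(round(nchar(ins) * (1 + jit))))
          ins <- if (new_len <= nchar(ins)) substr(ins, 1, new_len)
          else paste0(ins, random_dna(new_len - nchar(ins)))
        }
        if (isTRUE(model$seq_replace)) {
          ins <- strrep(sample(c("A", "C", "G", "T"), 1), nchar(ins))
          nerr <- nchar(ins)
        }
        mut <- mutate_seq(ins, model$seq_error_rate)
        nerr <- nerr + mut$n
        alt_al <- paste0(substr(alt_al, 1, 1), mut$seq)
      }
      rows[[length(rows) + 1L]] <- list(
        contig = r$contig, pos = pos, ref = ref_al, alt = alt_al,
        id = r$id, qual = r$qual, fmt = r$fmt[[1]])
      ledger[[length(ledger) + 1L]] <- data.frame(
        id = r$id, action = "kept", shift = shift, jitter_frac = jit,
        n_errors = nerr,
        new_size = abs(nchar(alt_al) - nchar(ref_al)),
        stringsAsFactors = FALSE)
    }
    # novel records placed midway between existing footprints
    n_novel <- stats::rbinom(1, nrow(truth), model$novel_rate)
    if (n_novel > 0) {
      widths <- Biostrings::width(reference)
      occupied <- sort(c(1000, truth$start[truth$contig == names(reference)[1]],
                         widths[1] - 1000))
      gaps <- which(diff(occupied) > 2500)
      gaps <- utils::head(gaps, n_novel)
      for (k in seq_along(gaps)) {
        p0 <- occupied[gaps[k]] + 1250L
        anchor <- ref_slice(reference, names(reference)[1], p0, p0 + 1)
        size <- sample(60:500, 1)
        id <- sprintf("novel_%d", k)
        rows[[length(rows) + 1L]] <- list(
          contig = names(reference)[1], pos = p0 + 1, ref = anchor,
          alt = paste0(anchor, random_dna(size)), id = id,
          qual = round(stats::runif(1, 20, 60), 1),
          fmt = truth$fmt[[1]])
        ledger[[length(ledger) + 1L]] <- data.frame(
          id = id, action = "novel", shift = 0L, jitter_frac = 0,
          n_errors = 0L, new_size = size, stringsAsFactors = FALSE)
      }
    }
    smp <- attr(truth, "samples")
    comp <- sv_records(
      contig = vapply(rows, `[[`, "", "contig"),
      pos = vapply(rows, `[[`, 0, "pos"),
      ref = vapply(rows, `[[`, "", "ref"),
      alt = vapply(rows, `[[`, "", "alt"),
      id = vapply(rows, `[[`, "", "id"),
      qual = vapply(rows, `[[`, 0, "qual"),
      filter = "PASS",
      gt = lapply(rows, `[[`, "fmt"),
      samples = smp, source = "comp"
    )
    comp <- sort_records(comp)
    list(comp = comp, ledger = do.call(rbind, ledger))
  })
}

#' Generate the worked eight-allele tandem-repeat locus
#'
#' One tandem-repeat locus on a random contig: a 29-bp motif array into
#' which eight insertion alleles are placed across 10 samples, with +2, +3,
#' +4 and +5 motif copies, two representations each. Within a copy-number
#' pair the two representations carry the identical inserted sequence at
#' anchors one motif apart (29 bp, well under 500 bp) inside the periodic
#' array, so their local haplotypes are literally identical (sequence
#' similarity 1); across copy numbers the size similarity is at most 4/5,
#' below the 95% merging threshold. Four alleles are therefore redundant
#' representations and a correct merge keeps exactly one allele per copy
#' number.
#'
#' @param seed Integer seed.
#' @param motif_len Motif length in bp (29 by default).
#' @param array_copies Motif copies planted in the reference.
#' @return A list: `reference` (`DNAStringSet`), `records` (8-allele
#'   multi-sample `sv_records`), `annotations` (data.frame `id`, `contig`,
#'   `start`, `locus_id`, `motif`, `copy_diff`), `motif`, `array`
#'   (0-based half-open coordinates of the planted array).
#' @export
make_fig4a_locus <- function(seed = 42, motif_len = 29, array_copies = 12) {
  with_seed(seed, {
    motif <- random_dna(motif_len)
    ref <- make_reference(n_contigs = 1, length = 20000, seed = seed + 1,
                          repeats = data.frame(contig = 1, start = 10000,
                                               motif = motif,
                                               copies = array_copies))
    contig <- names(ref$seq)[1]
    a0 <- 10000L # array start, 0-based, phase 0
    copy_diffs <- c(2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L)
    # pair members anchored at phase-0 positions a0 and a0 + motif_len
    anchors <- ifelse(seq_along(copy_diffs) %% 2 == 1, a0, a0 + motif_len)
    smp <- sprintf("S%02d", 1:10)
    rows <- lapply(seq_along(copy_diffs), function(i) {
      p0 <- anchors[i]
      anchor_base <- ref_slice(ref$seq, contig, p0, p0 + 1)
      gt <- stats::setNames(as.list(rep("0/0", 10)), smp)
      gt[[smp[i]]] <- "0/1"
      list(pos = p0 + 1,
           ref = anchor_base,
           alt = paste0(anchor_base, strrep(motif, copy_diffs[i])),
           gt = gt)
    })
    recs <- sv_records(
      contig = contig,
      pos = vapply(rows, `[[`, 0, "pos"),
      ref = vapply(rows, `[[`, "", "ref"),
      alt = vapply(rows, `[[`, "", "alt"),
      id = sprintf("ins_plus%d_%s", copy_diffs, rep(c("a", "b"), 4)),
      qual = round(stats::runif(8, 30, 60), 1),
      filter = "PASS",
      gt = lapply(rows, `[[`, "gt"),
      samples = smp, source = "fig4a"
    )
    recs <- sort_records(recs)
    annotations <- data.frame(
      id = recs$id, contig = contig, start = recs$start,
      locus_id = "locus1", motif = motif,
      copy_diff = as.integer(sub("^ins_plus([0-9]+)_.*$", "\\1", recs$id)),
      stringsAsFactors = FALSE)
    list(reference = ref$seq, records = recs, annotations = annotations,
         motif = motif, array = c(a0, a0 + motif_len * array_copies))
  })
}

#' Write the tandem-repeat locus fixture to disk
#'
#' Emits `reference.fa`, `fig4a.vcf` and `fig4a_tr.tsv` (the 5-column
#' annotation sidecar) for CLI or external use.
#'
#' @param locus The list returned by [make_fig4a_locus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fig4a_locus <- function(locus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(locus$reference, file.path(dir, "reference.fa"))
  write_sv_vcf(locus$records, file.path(dir, "fig4a.vcf"),
               reference = locus$reference)
  utils::write.table(
    locus$annotations[, c("contig", "start", "locus_id", "motif", "copy_diff")],
    file.path(dir, "fig4a_tr.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
  invisible(dir)
}
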