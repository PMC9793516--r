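# Redundancy-aware merging: genotype compatibility, clustering,
# representative selection, genotype consolidation and whole-run invariants.

test_that("intra-sample genotype compatibility follows haplotype slots", {
  expect_false(gt_compatible("1/1", "0/1"))
  expect_false(gt_compatible("1/1", "1/1"))
  expect_true(gt_compatible("1|0", "0|1"))
  expect_false(gt_compatible("1|0", "1|0"))
  expect_true(gt_compatible("0/1", "0/1"))  # unphased hets may lie opposite
  expect_true(gt_compatible("0/0", "1/1"))  # no ALT on one side
  expect_true(gt_compatible("./.", "1/1"))  # missing treated as compatible
})

test_that("chain clustering is the connected components of passing matches", {
  m <- chain_clusters(c("A", "B", "C"),
                      data.frame(a = c("A", "B"), b = c("B", "C")))
  expect_equal(length(unique(m)), 1)
  m2 <- chain_clusters(c("A", "B", "C"), data.frame(a = character(0), b = character(0)))
  expect_equal(length(unique(m2)), 3)
  m3 <- chain_clusters(c("A", "B", "C", "D"),
                       data.frame(a = c("A", "C"), b = c("B", "D")))
  expect_equal(length(unique(m3)), 2)
  expect_equal(m3[["A"]], m3[["B"]])
  expect_false(m3[["A"]] == m3[["C"]])
})

test_that("representative selection honors first, maxqual and common", {
  cl <- sv_records(contig = "chr1", pos = c(100, 90, 120), ref = "A",
                   alt = vapply(1:3, function(i) paste0("A", rand_dna(60)), ""),
                   qual = c(10, 50, 30),
                   gt = list(list(S1 = "0/1", S2 = "0/0"),
                             list(S1 = "1/1", S2 = "1/1"),
                             list(S1 = "0/1", S2 = "0/1")),
                   samples = c("S1", "S2"), source = "t")
  expect_equal(choose_representative(cl, "first"), 2) # most upstream (pos 90)
  expect_equal(choose_representative(cl, "maxqual"), 2) # QUAL 50
  # ALT counts: 1, 4, 2 -> common picks row 2
  expect_equal(choose_representative(cl, "common"), 2)
  cl$qual <- NA_real_
  expect_equal(choose_representative(cl, "maxqual"), 2) # falls back to first
})

test_that("genotype consolidation sums ALT counts with diploid saturation", {
  mk <- function(g1, g2) sv_records(
    contig = "chr1", pos = c(100, 100), ref = "A",
    alt = paste0("A", strrep("T", 60)),
    gt = list(list(S1 = g1), list(S1 = g2)), samples = "S1", source = "t")
  gt_out <- function(g1, g2) {
    f <- consolidate_genotypes(mk(g1, g2), 1, "S1")
    f[["S1"]][["GT"]]
  }
  expect_equal(gt_out("0/1", "0/1"), "1/1")
  expect_equal(gt_out("0/1", "0/0"), "0/1")
  expect_equal(gt_out("0/1", "1/1"), "1/1") # saturated at 2
  expect_equal(attr(consolidate_genotypes(mk("0/1", "1/1"), 1, "S1"), "saturated"), 1)
  expect_equal(gt_out("./.", "./."), "./.")
})

test_that("exact duplicates always collapse to one representative", {
  ref <- make_reference(1, 3e4, seed = 61)
  p <- 5000
  anchor <- ref_slice_test(ref$seq, p)
  dup <- sv_records(contig = "ctg1", pos = c(p, p), ref = anchor,
                    alt = paste0(anchor, rand_dna(100)),
                    id = c("v1", "v2"),
                    gt = list(list(S1 = "0/1"), list(S1 = "0/1")),
                    samples = "S1", source = "t")
  dup$alt[2] <- dup$alt[1]
  cl <- sv_collapse(dup, reference = ref$seq)
  expect_equal(nrow(cl$kept), 1)
  expect_equal(nrow(cl$removed), 1)
  expect_equal(unname(cl$clusters[["v2"]]), "v1")
  # consolidated genotype: two hets become hom
  expect_equal(cl$kept$fmt[[1]]$S1[["GT"]], "1/1")
  # removed record is annotated with its representative
  expect_equal(cl$removed$info[[1]]$MatchId, "v1")
})

test_that("hap mode collapses exactly the constructed homozygous loci", {
  withr::with_seed(71, {
    ref <- make_reference(1, 1e5, seed = 71)
    n <- 12
    k <- 5 # identical-on-both-haplotypes loci
    pos <- sort(sample(seq(2000, 90000, by = 4000), n))
    hom <- sort(sample(n, k))
    rows1 <- list(); rows2 <- list()
    for (i in seq_len(n)) {
      anchor <- ref_slice_test(ref$seq, pos[i])
      seq1 <- rand_dna(150)
      rows1[[i]] <- list(pos = pos[i], ref = anchor,
                         alt = paste0(anchor, seq1), gt = "1|0")
      seq2 <- if (i %in% hom) seq1 else rand_dna(150)
      rows2[[i]] <- list(pos = pos[i], ref = anchor,
                         alt = paste0(anchor, seq2), gt = "0|1")
    }
    mk <- function(rows, src) sv_records(
      contig = "ctg1", pos = vapply(rows, `[[`, 0, "pos"),
      ref = vapply(rows, `[[`, "", "ref"),
      alt = vapply(rows, `[[`, "", "alt"),
      gt = lapply(rows, function(r) list(S1 = r$gt)),
      samples = "S1", source = src)
    hap1 <- mk(rows1, "h1")
    hap2 <- mk(rows2, "h2")
    cl <- sv_collapse(list(hap1, hap2), reference = ref$seq, hap = TRUE)
    expect_equal(nrow(cl$removed), k)
    # heterozygous non-identical loci remain separate
    expect_equal(nrow(cl$kept), 2 * n - k)
    # merged loci become homozygous
    merged_reps <- unique(cl$clusters[names(cl$clusters) != cl$clusters])
    for (id in merged_reps) {
      g <- cl$kept$fmt[[which(cl$kept$id == id)]]$S1[["GT"]]
      expect_equal(g, "1/1")
    }
  })
})

test_that("chain mode merges transitively linked variants into one cluster", {
  # A ~ B and B ~ C pass, A ~ C fails on refdist; chain gives one cluster
  ref_str <- rand_dna(10000)
  ref <- ref_from_string(ref_str)
  ins <- rand_dna(2000)
  anchors <- c(3000, 3400, 3800)
  abase <- vapply(anchors, function(p) substr(ref_str, p, p), "")
  recs <- sv_records(contig = "chr1", pos = anchors, ref = abase,
                     alt = paste0(abase, ins), id = c("A", "B", "C"),
                     source = "t")
  p <- collapse_match_params(refdist = 500, pctseq = 0.7, pctsize = 0.7)
  mAC <- build_match(recs[1, ], recs[3, ], p, ref)
  expect_false(mAC$state) # not a direct match
  no_chain <- sv_collapse(recs, reference = ref, params = p)
  expect_equal(nrow(no_chain$kept), 2)
  chained <- sv_collapse(recs, reference = ref, params = p, chain = TRUE)
  expect_equal(nrow(chained$kept), 1)
  expect_equal(chained$kept$id, "A")
})

test_that("collapse conservation, idempotence and ALT-count conservation hold", {
  for (s in c(81, 82, 83)) {
    ref <- make_reference(1, 1e5, seed = s)
    truth <- implant_svs(ref, n_del = 8, n_ins = 8, seed = s, n_samples = 2,
                         size_range = c(60, 300))
    # a perturbed replicate of every record, interleaved: redundant callset
    dup <- perturb_callset(truth, ref,
                           perturbation_model(pos_shift = c(0, 20),
                                              seq_error_rate = 0.01,
                                              seed = s + 1))$comp
    dup$id <- paste0("dup_", dup$id)
    input <- zip_variants(truth, dup)
    cl <- suppressWarnings( # hom + hom duplicates saturate by design
      sv_collapse(input, reference = ref$seq,
                  params = collapse_match_params(pctseq = 0.9, pctsize = 0.9)))
    expect_equal(nrow(cl$kept) + nrow(cl$removed), nrow(input))
    # idempotence: a second collapse removes nothing
    again <- sv_collapse(cl$kept, reference = ref$seq,
                         params = collapse_match_params(pctseq = 0.9, pctsize = 0.9))
    expect_equal(nrow(again$removed), 0)
    # total ALT-allele conservation up to the documented diploid saturation
    alt_total <- function(recs) sum(vapply(recs$fmt, function(f) {
      sum(vapply(f, function(x) {
        v <- gt_alt_count_test(x[["GT"]])
        if (is.na(v)) 0L else v
      }, 0L))
    }, 0L))
    before <- alt_total(input)
    after <- alt_total(cl$kept)
    if (cl$n_saturated == 0) {
      expect_equal(after, before)
    } else {
      expect_lt(after, before)
      expect_gte(after, before - 2L * cl$n_saturated)
    }
    # monotonicity: stricter thresholds never remove more
    stricter <- suppressWarnings(
      sv_collapse(input, reference = ref$seq,
                  params = collapse_match_params(pctseq = 0.99, pctsize = 0.99)))
    expect_lte(nrow(stricter$removed), nrow(cl$removed))
  }
})

test_that("chain-mode collapse is idempotent for any keep strategy", {
  for (s in c(91, 92)) {
    ref <- make_reference(1, 8e4, seed = s)
    truth <- implant_svs(ref, n_del = 6, n_ins = 6, seed = s,
                         size_range = c(60, 250))
    dup <- perturb_callset(truth, ref,
                           perturbation_model(pos_shift = c(0, 15), seed = s + 1))$comp
    dup$id <- paste0("dup_", dup$id)
    input <- zip_variants(truth, dup)
    for (keep in c("first", "maxqual", "common")) {
      cl <- suppressWarnings(
        sv_collapse(input, reference = ref$seq, chain = TRUE, keep = keep,
                    params = collapse_match_params(pctseq = 0.9, pctsize = 0.9)))
      again <- sv_collapse(cl$kept, reference = ref$seq, chain = TRUE, keep = keep,
                           params = collapse_match_params(pctseq = 0.9, pctsize = 0.9))
      expect_equal(nrow(again$removed), 0)
    }
  }
})
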