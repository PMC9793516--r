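# Pairwise similarity metrics and putative-match construction.

make_del <- function(pos, len, contig = "chr1", ref_seq = NULL) {
  # sequence-resolved DEL over [pos, pos + len) (0-based), anchored at pos
  if (is.null(ref_seq)) {
    sv_records(contig = contig, pos = pos, ref = "A", alt = "<DEL>",
               svtype = "DEL", svlen = len, source = "t")
  } else {
    anchor <- substr(ref_seq, pos, pos)
    rec(pos, paste0(anchor, substr(ref_seq, pos + 1, pos + len)), anchor,
        contig = contig)
  }
}

test_that("the reference-distance gate is the printed strict inequality", {
  a <- make_del(101, 100) # span [101, 201)
  b <- make_del(651, 100) # span [651, 751)
  expect_true(reference_distance_ok(a, b, 500))  # 650 < 700
  b2 <- make_del(702, 99)  # span [702, 801)
  expect_false(reference_distance_ok(a, b2, 500)) # 702 < 701 is false
  expect_true(reference_distance_ok(a, a, 0))     # identical spans self-overlap
  c_other <- make_del(101, 100, contig = "chr2")
  expect_false(reference_distance_ok(a, c_other, 500))
})

test_that("reciprocal overlap divides shared bases by the maximum span", {
  a <- make_del(101, 100) # [101, 201)
  expect_equal(reciprocal_overlap(a, a), 1.0)
  b <- make_del(151, 100) # [151, 251)
  expect_equal(reciprocal_overlap(a, b), 0.5)
  far <- make_del(1001, 100)
  expect_equal(reciprocal_overlap(a, far), 0.0)
  # insertion spans are expanded by half their length both ways
  i1 <- rec(100, "A", paste0("A", rand_dna(100)))
  i2 <- rec(150, "A", paste0("A", rand_dna(100)))
  # expanded spans [49,150) and [99,200): overlap 51 over span 101
  expect_equal(reciprocal_overlap(i1, i2), 51 / 101)
})

test_that("size similarity is min length over max length", {
  s <- function(l1, l2) size_similarity(list(svlen = l1), list(svlen = l2))
  expect_equal(s(500, 500), 1.0)
  expect_equal(s(538, 580), 538 / 580)
  expect_equal(round(s(538, 580), 4), 0.9276)
  expect_equal(s(50, 100), 0.5)
})

test_that("haplotypes substitute each allele over the shared context", {
  refseq <- "ACGTACGTACGTACGTACGT"
  ref <- ref_from_string(refseq)
  # identical records give identical haplotypes
  a <- rec(5, "A", "ATTT")
  expect_equal(build_haplotypes(a, a, ref)[1], build_haplotypes(a, a, ref)[2])
  # two INS at the same anchor differing by one base: 1 substitution apart
  b1 <- rec(5, "A", "AAC")
  b2 <- rec(5, "A", "AAG")
  h <- build_haplotypes(b1, b2, ref)
  expect_equal(nchar(h[1]), nchar(h[2]))
  expect_equal(sum(strsplit(h[1], "")[[1]] != strsplit(h[2], "")[[1]]), 1)
  # S1 < S2: H1 begins with the applied allele, H2 with ref[S1:S2]
  d1 <- rec(3, substr(refseq, 3, 8), substr(refseq, 3, 3)) # DEL [3,8) 0-based
  d2 <- rec(7, substr(refseq, 7, 12), substr(refseq, 7, 7))
  h2 <- build_haplotypes(d1, d2, ref)
  expect_equal(h2[1], substr(refseq, 9, 12))  # ref[E1:end) after empty allele
  expect_true(startsWith(h2[2], substr(refseq, 4, 7))) # ref[S1:S2)
  # symbolic alleles cannot be sequence-compared
  sym <- sv_records(contig = "chr1", pos = 5, ref = "A", alt = "<DEL>",
                    svtype = "DEL", svlen = 5, source = "t")
  expect_error(build_haplotypes(sym, a, ref), "symbolic")
})

test_that("sequence similarity follows 1 - ed/totlen with hand values", {
  ref <- ref_from_string(strrep("T", 50))
  a <- rec(10, "T", "TAAAA")
  b <- rec(10, "T", "TAAAT")
  # haplotypes TAAAA / TAAAT: ed 1, totlen 10
  expect_equal(sequence_similarity(a, b, ref), 1 - 1 / 10)
  expect_equal(sequence_similarity(a, a, ref), 1.0)
  # the alternative symmetric normalization doubles the penalty
  expect_equal(sequence_similarity(a, b, ref, symmetric = TRUE), 1 - 2 / 10)
})

test_that("sequence similarity agrees exactly with the DP oracle (random suite)", {
  withr::with_seed(21, {
    ref_str <- rand_dna(2000)
    ref <- ref_from_string(ref_str)
    for (i in 1:60) {
      p1 <- sample(100:1800, 1)
      p2 <- p1 + sample(0:40, 1)
      if (runif(1) < 0.5) {
        a <- rec(p1, substr(ref_str, p1, p1), paste0(substr(ref_str, p1, p1), rand_dna(sample(30:80, 1))))
        b <- rec(p2, substr(ref_str, p2, p2), paste0(substr(ref_str, p2, p2), rand_dna(sample(30:80, 1))))
      } else {
        a <- make_del(p1, sample(30:60, 1), ref_seq = ref_str)
        b <- make_del(p2, sample(30:60, 1), ref_seq = ref_str)
      }
      h <- build_haplotypes(a, b, ref)
      ed <- dp_levenshtein(h[1], h[2])
      expected <- if (sum(nchar(h)) == 0) 1 else
        min(1, max(0, 1 - ed / sum(nchar(h))))
      expect_equal(sequence_similarity(a, b, ref), expected)
    }
  })
})

test_that("metric symmetry holds under argument swap (property)", {
  withr::with_seed(31, {
    ref_str <- rand_dna(3000)
    ref <- ref_from_string(ref_str)
    for (i in 1:25) {
      p1 <- sample(200:2500, 1)
      p2 <- p1 + sample(-100:100, 1)
      mk <- function(p) {
        if (runif(1) < 0.5)
          rec(p, substr(ref_str, p, p),
              paste0(substr(ref_str, p, p), rand_dna(sample(50:200, 1))))
        else make_del(p, sample(50:200, 1), ref_seq = ref_str)
      }
      a <- mk(p1)
      b <- mk(p2)
      expect_equal(reciprocal_overlap(a, b), reciprocal_overlap(b, a))
      expect_equal(size_similarity(a, b), size_similarity(b, a))
      expect_equal(sequence_similarity(a, b, ref), sequence_similarity(b, a, ref))
      m <- build_match(a, b, match_params(), ref)
      expect_true(m$recovl >= 0 && m$recovl <= 1)
      expect_true(m$sizesim >= 0 && m$sizesim <= 1)
      expect_true(is.na(m$seqsim) || (m$seqsim >= 0 && m$seqsim <= 1))
      expect_true(m$truscore >= 0 && m$truscore <= 100)
    }
  })
})

test_that("build_match gates, TruScore averaging and identity behave", {
  ref_str <- rand_dna(2000)
  ref <- ref_from_string(ref_str)
  a <- rec(500, substr(ref_str, 500, 500),
           paste0(substr(ref_str, 500, 500), rand_dna(100)))
  # identity passes the strictest thresholds
  m <- build_match(a, a, match_params(refdist = 0, pctseq = 1, pctsize = 1,
                                      pctovl = 0), ref)
  expect_true(m$state)
  expect_equal(m$truscore, 100)
  expect_equal(m$start_distance, 0)
  # DEL vs INS fails on type regardless of other metrics
  d <- make_del(500, 100, ref_seq = ref_str)
  md <- build_match(a, d, match_params(), ref)
  expect_false(md$state)
  expect_false(md$type_match)
  # typematch off lets the pair be judged on metrics alone
  md2 <- build_match(a, d, match_params(typematch = FALSE, pctseq = 0,
                                        pctsize = 0), ref)
  expect_true(md2$state)
  # TruScore is the mean of the fractional metrics times 100
  expect_equal(mean(c(0.8, 0.9, 0.7)) * 100, 80)
  b <- rec(520, substr(ref_str, 520, 520),
           paste0(substr(ref_str, 520, 520), rand_dna(90)))
  mb <- build_match(a, b, match_params(), ref)
  expect_equal(mb$truscore,
               100 * mean(c(mb$recovl, mb$sizesim, mb$seqsim)))
  # with pctseq = 0 sequence similarity is skipped and excluded from the mean
  mb0 <- build_match(a, b, match_params(pctseq = 0))
  expect_true(is.na(mb0$seqsim))
  expect_equal(mb0$truscore, 100 * mean(c(mb0$recovl, mb0$sizesim)))
  # signed breakpoint distances are base minus comp
  expect_equal(mb$start_distance, a$start - b$start)
  expect_equal(mb$end_distance, a$end - b$end)
})

test_that("lowering any threshold never decreases the passing-pair count", {
  withr::with_seed(41, {
    ref <- make_reference(1, 3e4, seed = 41)
    truth <- implant_svs(ref, n_del = 5, n_ins = 5, seed = 41, min_gap = 200,
                         size_range = c(50, 300))
    comp <- perturb_callset(truth, ref,
                            perturbation_model(pos_shift = c(0, 80),
                                               seq_error_rate = 0.05,
                                               seed = 42))$comp
    count_passing <- function(p) {
      sum(build_match_matrix(truth, comp, p, ref$seq)$state)
    }
    base <- match_params(refdist = 200, pctseq = 0.9, pctsize = 0.9, pctovl = 0.3)
    n0 <- count_passing(base)
    expect_gte(count_passing(match_params(refdist = 400, pctseq = 0.9,
                                          pctsize = 0.9, pctovl = 0.3)), n0)
    expect_gte(count_passing(match_params(refdist = 200, pctseq = 0.5,
                                          pctsize = 0.9, pctovl = 0.3)), n0)
    expect_gte(count_passing(match_params(refdist = 200, pctseq = 0.9,
                                          pctsize = 0.5, pctovl = 0.3)), n0)
    expect_gte(count_passing(match_params(refdist = 200, pctseq = 0.9,
                                          pctsize = 0.9, pctovl = 0)), n0)
  })
})
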