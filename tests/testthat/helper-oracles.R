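# Independent oracles and small fixture builders used across the suite.

# Quadratic dynamic-programming Levenshtein distance, written independently
# of the package's edit-distance path (row-vectorized for speed; the
# insertion recurrence cur[j] = min(cand[j], cur[j-1] + 1) is solved as a
# running minimum: cur[j] = j + cummin(c(i, cand - 1:m))[j + 1]).
dp_levenshtein <- function(a, b) {
  s <- utf8ToInt(a)
  t <- utf8ToInt(b)
  n <- length(s)
  m <- length(t)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cand <- pmin(prev[-1] + 1L, prev[-(m + 1)] + (s[i] != t))
    prev <- c(i, seq_len(m) + cummin(c(i, cand - seq_len(m)))[-1])
  }
  prev[m + 1]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# One-contig DNAStringSet reference from a raw string.
ref_from_string <- function(s, name = "chr1") {
  Biostrings::DNAStringSet(stats::setNames(s, name))
}

# Convenience single-record builder on a given contig.
rec <- function(pos, ref, alt, contig = "chr1", id = NULL, qual = NA,
                gt = NULL, filter = "PASS", source = "test", ...) {
  sv_records(contig = contig, pos = pos, ref = ref, alt = alt, id = id,
             qual = qual, gt = gt, filter = filter, source = source, ...)
}

# 1-based single-base reference lookup on the first contig.
ref_slice_test <- function(ref, pos1) {
  substr(as.character(ref[[1]]), pos1, pos1)
}

# Independent ALT-allele counter for GT strings.
gt_alt_count_test <- function(gt) {
  if (is.null(gt) || is.na(gt)) return(NA_integer_)
  al <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (all(is.na(al))) return(NA_integer_)
  sum(al > 0, na.rm = TRUE)
}

# Exhaustive best-assignment oracle: over all matchings of passing pairs,
# maximize (number of matches, total TruScore). Returns the selected pair
# indices (rows of `pairs`).
brute_force_assignment <- function(pairs) {
  pass <- which(pairs$state)
  best <- list(card = -1, score = -Inf, sel = integer(0))
  recurse <- function(remaining, sel, used_b, used_c) {
    if (!length(remaining)) {
      card <- length(sel)
      score <- sum(pairs$truscore[sel])
      if (card > best$card || (card == best$card && score > best$score))
        best <<- list(card = card, score = score, sel = sel)
      return(invisible())
    }
    i <- remaining[1]
    rest <- remaining[-1]
    if (!(pairs$base_id[i] %in% used_b) && !(pairs$comp_id[i] %in% used_c))
      recurse(rest, c(sel, i), c(used_b, pairs$base_id[i]),
              c(used_c, pairs$comp_id[i]))
    recurse(rest, sel, used_b, used_c)
  }
  recurse(pass, integer(0), character(0), character(0))
  best$sel
}

# Random chunk instance on which the greedy sweep is optimal by
# construction: a planted matching of passing pairs with distinct TruScores,
# plus optional passing decoys whose endpoints are both covered by planted
# pairs of strictly higher score.
make_planted_instance <- function(n_base, n_comp, n_decoys = 2) {
  k <- min(n_base, n_comp)
  planted_b <- sample(n_base, k)
  planted_c <- sample(n_comp, k)
  scores <- sort(sample(seq(60, 100, by = 0.25), k), decreasing = TRUE)
  rows <- data.frame(
    base_id = paste0("b", planted_b), comp_id = paste0("c", planted_c),
    base_start = planted_b * 10L, comp_start = planted_c * 10L,
    seqsim = NA_real_, sizesim = NA_real_, recovl = NA_real_,
    start_distance = 0L, end_distance = 0L, type_match = TRUE,
    gt_match = NA, truscore = scores, state = TRUE,
    stringsAsFactors = FALSE)
  if (n_decoys > 0 && k >= 2) {
    lo <- min(scores)
    for (d in seq_len(n_decoys)) {
      i <- sample(k, 2)
      rows <- rbind(rows, data.frame(
        base_id = paste0("b", planted_b[i[1]]),
        comp_id = paste0("c", planted_c[i[2]]),
        base_start = planted_b[i[1]] * 10L,
        comp_start = planted_c[i[2]] * 10L,
        seqsim = NA_real_, sizesim = NA_real_, recovl = NA_real_,
        start_distance = 0L, end_distance = 0L, type_match = TRUE,
        gt_match = NA, truscore = lo - d * 0.5, state = TRUE,
        stringsAsFactors = FALSE))
    }
  }
  # failing pairs for the rest of the matrix (never assignable)
  rows
}
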