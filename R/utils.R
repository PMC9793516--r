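# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a local, restored RNG state
#'
#' All simulator randomness runs through this so generation is reproducible
#' from an explicit seed and never perturbs the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Split a GT string ("0/1", "1|0", "./.") into an integer allele vector.
# Missing alleles are NA; a fully missing GT gives all-NA.
gt_alleles <- function(gt) {
  if (is.null(gt) || is.na(gt) || gt == "" || gt == ".") return(NA_integer_)
  parts <- strsplit(gt, "[/|]")[[1]]
  suppressWarnings(as.integer(ifelse(parts == ".", NA, parts)))
}

gt_is_phased <- function(gt) {
  !is.null(gt) && !is.na(gt) && grepl("|", gt, fixed = TRUE)
}

# Number of ALT alleles carried by a genotype; NA when fully missing.
gt_alt_count <- function(gt) {
  al <- gt_alleles(gt)
  if (all(is.na(al))) return(NA_integer_)
  sum(al > 0, na.rm = TRUE)
}

# Sorted allele indices for phase-insensitive genotype comparison.
gt_sorted <- function(gt) sort(gt_alleles(gt), na.last = TRUE)

# GT string for a sample from a record's per-sample FORMAT map.
record_gt <- function(fmt, sample) {
  f <- fmt[[sample]]
  if (is.null(f)) return(NA_character_)
  g <- f[["GT"]]
  if (is.null(g)) NA_character_ else g
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), ".", formatC(x, format = "f", digits = digits))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
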