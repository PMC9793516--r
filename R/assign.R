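# Match assignment: turn the raveled matrix of putative matches into a
# classification of every base and comp record.

# Sort order for the greedy sweep: passing pairs first, then descending
# TruScore; ties broken by (base start, comp start) for determinism.
ravel_order <- function(pairs) {
  order(-pairs$state, -pairs$truscore, pairs$base_start, pairs$comp_start,
        method = "radix")
}

#' Single-best match assignment
#'
#' Greedy sweep over the raveled match matrix in descending TruScore order
#' (passing pairs first): a pair is emitted with its threshold state when
#' neither member has been consumed; when either member was already used the
#' pair's state becomes false and its unused member falls through to FN/FP.
#' Every input record appears exactly once in the classification.
#'
#' @param pairs Match table from [build_match_matrix()].
#' @param base_ids,comp_ids All record ids of the chunk (records without any
#'   putative match are classified FN/FP).
#' @return A list with `pairs` (emitted pairs with final state),
#'   `base_class` and `comp_class` (named `"TP"`/`"FN"` and `"TP"`/`"FP"`
#'   vectors).
#' @export
assign_single_best <- function(pairs, base_ids, comp_ids) {
  base_class <- stats::setNames(rep("FN", length(base_ids)), base_ids)
  comp_class <- stats::setNames(rep("FP", length(comp_ids)), comp_ids)
  emitted <- list()
  if (nrow(pairs)) {
    used_base <- character(0)
    used_comp <- character(0)
    for (i in ravel_order(pairs)) {
      p <- pairs[i, ]
      if (p$base_id %in% used_base || p$comp_id %in% used_comp) next
      used_base <- c(used_base, p$base_id)
      used_comp <- c(used_comp, p$comp_id)
      emitted[[length(emitted) + 1L]] <- p
      if (p$state) {
        base_class[p$base_id] <- "TP"
        comp_class[p$comp_id] <- "TP"
      }
    }
  }
  emitted <- if (length(emitted)) {
    e <- do.call(rbind, emitted)
    rownames(e) <- NULL
    e
  } else empty_match_table()
  list(pairs = emitted, base_class = base_class, comp_class = comp_class)
}

#' Multi-match assignment
#'
#' Sorts each row and column of the match matrix independently so the
#' highest-scoring passing partner of every base and comp record is
#' reported; a record may participate in several reported matches.
#'
#' @inheritParams assign_single_best
#' @return Same shape as [assign_single_best()]; `pairs` holds the union of
#'   row-best and column-best passing pairs.
#' @export
assign_multi <- function(pairs, base_ids, comp_ids) {
  base_class <- stats::setNames(rep("FN", length(base_ids)), base_ids)
  comp_class <- stats::setNames(rep("FP", length(comp_ids)), comp_ids)
  keep <- pairs[which(pairs$state), , drop = FALSE]
  if (!nrow(keep))
    return(list(pairs = empty_match_table(),
                base_class = base_class, comp_class = comp_class))
  o <- ravel_order(keep)
  keep <- keep[o, , drop = FALSE]
  row_best <- keep[!duplicated(keep$base_id), , drop = FALSE]
  col_best <- keep[!duplicated(keep$comp_id), , drop = FALSE]
  emitted <- unique(rbind(row_best, col_best))
  rownames(emitted) <- NULL
  base_class[unique(keep$base_id)] <- "TP"
  comp_class[unique(keep$comp_id)] <- "TP"
  list(pairs = emitted, base_class = base_class, comp_class = comp_class)
}
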