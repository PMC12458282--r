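# Over-representation analysis of gene lists against gene-set collections.

#' Hypergeometric over-representation analysis
#'
#' For each set: the set is first intersected with the background (standard
#' ORA convention), the overlap with the query is counted, the upper-tail
#' hypergeometric probability of at least that overlap is computed
#' (equivalent to a
#' one-sided Fisher's exact test on the 2x2 table), fold enrichment is
#' (overlap/query_size) / (set_in_background/background_size), and BH FDR
#' is applied across sets.
#'
#' @param query character vector of gene ids (must be a subset of
#'   `background`).
#' @param background character vector of gene ids (the expressed universe,
#'   at least 2 genes).
#' @param sets a `gene_set_collection`.
#' @return data.frame with columns `set_name`, `overlap`, `set_size`,
#'   `query_size`, `background_size`, `fold_enrichment`, `p`, `fdr`.
#' @export
hypergeometric_enrichment <- function(query, background, sets) {
  query <- unique(query)
  background <- unique(background)
  if (length(background) < 2) {
    iscape_error("value_error", "background must contain >= 2 genes")
  }
  if (!all(query %in% background)) {
    iscape_error("value_error", "query must be a subset of the background")
  }
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    s_bg <- intersect(sets$sets[[nm]], background)
    m <- length(s_bg)
    ov <- length(intersect(query, s_bg))
    p <- if (m == 0) 1 else
      stats::phyper(ov - 1, m, n_bg - m, n_q, lower.tail = FALSE)
    fold <- if (m == 0 || n_q == 0) 0 else (ov / n_q) / (m / n_bg)
    data.frame(set_name = nm, overlap = ov, set_size = m,
               query_size = n_q, background_size = n_bg,
               fold_enrichment = fold, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  out
}
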