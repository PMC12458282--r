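# Cross-disease feature landscape: pooled effects and FDR per (feature,
# disease), significance filtering, and blood-vs-tissue overlap and
# concordance.

# Internal constructor shared with the synthetic generator.
new_feature_landscape <- function(effect, fdr, feature_type, compartment,
                                  k = NULL) {
  stopifnot(identical(dim(effect), dim(fdr)))
  structure(list(effect = effect,
                 fdr = fdr,
                 k = k,
                 feature_ids = rownames(effect),
                 feature_type = feature_type,
                 disease_ids = colnames(effect),
                 compartment = compartment,
                 missing = is.na(effect)),
            class = "feature_landscape")
}

#' @export
print.feature_landscape <- function(x, ...) {
  cat(sprintf("<feature_landscape> %d features x %d diseases (%s), %d missing cells\n",
              nrow(x$effect), ncol(x$effect), x$compartment, sum(x$missing)))
  invisible(x)
}

#' Assemble a feature landscape from per-disease pooled tables
#'
#' Takes the union of entities across diseases and aligns pooled estimates
#' and FDR into features x diseases matrices. Cells for (feature, disease)
#' pairs absent from a disease's table are explicitly missing (NA), never
#' silently zero. The per-cell number of contributing studies is retained.
#'
#' @param pooled_tables named list (by disease) of [meta_analyze()] tables.
#' @param compartment `"blood"` or `"tissue"`.
#' @param feature_type optional named character vector (by entity) of
#'   feature families; entities not covered get `"feature"`.
#' @return a `feature_landscape`.
#' @export
build_landscape <- function(pooled_tables, compartment = "blood",
                            feature_type = NULL) {
  if (length(pooled_tables) < 2) {
    iscape_error("value_error", "need tables for at least 2 diseases")
  }
  if (is.null(names(pooled_tables))) {
    iscape_error("value_error", "pooled_tables must be named by disease")
  }
  empty <- names(pooled_tables)[vapply(pooled_tables, nrow, integer(1)) == 0]
  if (length(empty) > 0) {
    iscape_error("pipeline_error", "empty pooled table for disease(s): %s",
                 paste(empty, collapse = ", "))
  }
  feats <- sort(unique(unlist(lapply(pooled_tables, `[[`, "entity"))))
  diseases <- names(pooled_tables)
  eff <- matrix(NA_real_, length(feats), length(diseases),
                dimnames = list(feats, diseases))
  fdr <- eff
  kmat <- eff
  for (d in diseases) {
    tb <- pooled_tables[[d]]
    eff[tb$entity, d] <- tb$estimate
    fdr[tb$entity, d] <- tb$fdr
    kmat[tb$entity, d] <- tb$k
  }
  ftype <- rep("feature", length(feats))
  names(ftype) <- feats
  if (!is.null(feature_type)) {
    hit <- intersect(feats, names(feature_type))
    ftype[hit] <- feature_type[hit]
  }
  new_feature_landscape(eff, fdr, unname(ftype), compartment, k = kmat)
}

# Subset a landscape to a row index (logical or integer).
.landscape_rows <- function(landscape, idx) {
  new_feature_landscape(landscape$effect[idx, , drop = FALSE],
                        landscape$fdr[idx, , drop = FALSE],
                        landscape$feature_type[idx],
                        landscape$compartment,
                        k = if (!is.null(landscape$k))
                          landscape$k[idx, , drop = FALSE])
}

#' Keep features significant in at least one disease
#'
#' Retains rows whose minimum FDR across diseases is below `threshold`
#' ("significant in at least one disease"). Idempotent.
#'
#' @param landscape a `feature_landscape`.
#' @param threshold FDR cutoff (default 0.05).
#' @return the filtered `feature_landscape`.
#' @export
significant_features <- function(landscape, threshold = 0.05) {
  minfdr <- apply(landscape$fdr, 1, function(x) {
    if (all(is.na(x))) Inf else min(x, na.rm = TRUE)
  })
  keep <- minfdr < threshold
  if (!any(keep)) {
    iscape_error("pipeline_error",
                 "no feature significant at FDR < %g", threshold)
  }
  .landscape_rows(landscape, keep)
}

# Significant feature ids for one disease at a threshold, optionally
# restricted to a feature family.
.significant_set <- function(landscape, disease, feature_type, threshold) {
  if (!disease %in% landscape$disease_ids) {
    iscape_error("lookup_error", "disease '%s' absent from the %s landscape",
                 disease, landscape$compartment)
  }
  idx <- rep(TRUE, length(landscape$feature_ids))
  if (!is.null(feature_type)) idx <- landscape$feature_type %in% feature_type
  f <- landscape$fdr[idx, disease]
  landscape$feature_ids[idx][!is.na(f) & f < threshold]
}

#' Blood-vs-tissue overlap of significant features for one disease
#'
#' Significant sets are taken per compartment at `threshold`;
#' `fraction_shared` is |intersection| / |union| (the per-compartment
#' fractions |intersection| / |compartment set| are also reported, since
#' the denominator convention is not universal).
#'
#' @param blood,tissue `feature_landscape`s for the two compartments.
#' @param disease disease id present in both.
#' @param feature_type optional feature-family restriction.
#' @param threshold FDR cutoff (default 0.05).
#' @return list with `shared`, `blood_only`, `tissue_only` (counts),
#'   `fraction_shared`, `fraction_blood`, `fraction_tissue`, and the id
#'   vectors.
#' @export
compartment_overlap <- function(blood, tissue, disease, feature_type = NULL,
                                threshold = 0.05) {
  b <- .significant_set(blood, disease, feature_type, threshold)
  t_ <- .significant_set(tissue, disease, feature_type, threshold)
  shared <- intersect(b, t_)
  un <- union(b, t_)
  list(disease = disease,
       shared = length(shared),
       blood_only = length(setdiff(b, t_)),
       tissue_only = length(setdiff(t_, b)),
       fraction_shared = if (length(un) == 0) NA_real_ else
         length(shared) / length(un),
       fraction_blood = if (length(b) == 0) NA_real_ else
         length(shared) / length(b),
       fraction_tissue = if (length(t_) == 0) NA_real_ else
         length(shared) / length(t_),
       shared_ids = shared)
}

#' Blood-vs-tissue concordance of pooled effects for one disease
#'
#' Spearman correlation over features shared between the compartments
#' (missing cells dropped pairwise). With `significant_both = TRUE`, only
#' features significant in both compartments enter.
#'
#' @param blood,tissue `feature_landscape`s.
#' @param disease disease id present in both.
#' @param feature_type optional feature-family restriction.
#' @param significant_both restrict to features significant in both
#'   compartments.
#' @param threshold FDR cutoff used when `significant_both`.
#' @return list with `rho`, `p`, `n`.
#' @export
compartment_concordance <- function(blood, tissue, disease,
                                    feature_type = NULL,
                                    significant_both = FALSE,
                                    threshold = 0.05) {
  for (l in list(blood, tissue)) {
    if (!disease %in% l$disease_ids) {
      iscape_error("lookup_error",
                   "disease '%s' absent from the %s landscape",
                   disease, l$compartment)
    }
  }
  bi <- rep(TRUE, length(blood$feature_ids))
  ti <- rep(TRUE, length(tissue$feature_ids))
  if (!is.null(feature_type)) {
    bi <- blood$feature_type %in% feature_type
    ti <- tissue$feature_type %in% feature_type
  }
  feats <- intersect(blood$feature_ids[bi], tissue$feature_ids[ti])
  if (significant_both) {
    feats <- intersect(
      feats, intersect(.significant_set(blood, disease, feature_type,
                                        threshold),
                       .significant_set(tissue, disease, feature_type,
                                        threshold)))
  }
  x <- blood$effect[feats, disease]
  y <- tissue$effect[feats, disease]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 4) {
    iscape_error("insufficient_data_error",
                 "only %d shared features for %s (need >= 4)", sum(ok),
                 disease)
  }
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Serialize a landscape as paired TSV matrices plus JSON annotations
#'
#' @param landscape a `feature_landscape`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_matrix(landscape$effect, file.path(dir, "effect.tsv"),
                   id_col = "feature_id")
  write_tsv_matrix(landscape$fdr, file.path(dir, "fdr.tsv"),
                   id_col = "feature_id")
  jsonlite::write_json(
    list(compartment = landscape$compartment,
         feature_ids = landscape$feature_ids,
         feature_type = landscape$feature_type,
         disease_ids = landscape$disease_ids),
    file.path(dir, "annotations.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
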