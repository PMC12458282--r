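# Module scoring and validation: aggregate per-sample module activity,
# ROC/AUC discrimination per study, stability-weighted enrichment
# summaries, size-matched permutation nulls, treatment-response prediction
# and severity correlation.

#' Aggregate module activity scores per sample
#'
#' Every feature row is z-scaled across the dataset's samples
#' (zero-variance features contribute 0), and a module's score per sample
#' is the sum of its scaled features. Features missing from the dataset are
#' skipped; per-module coverage is recorded. A module with no present
#' feature is scored NA with a warning.
#'
#' @param features a `feature_matrix` or list of them (stacked with
#'   [stack_features()]; module feature ids refer to the stacked,
#'   family-prefixed ids).
#' @param modules a `module_set`.
#' @return a `module_score_matrix`: list with `scores` (modules x samples),
#'   `module_ids`, `sample_ids`, `coverage` and the `scaling` used.
#' @export
module_scores <- function(features, modules) {
  stacked <- if (inherits(features, "feature_matrix") &&
                 features$feature_type == "combined") {
    features
  } else {
    stack_features(features)
  }
  z <- z_scale_rows(stacked$matrix)
  scores <- matrix(NA_real_, length(modules$modules), ncol(z),
                   dimnames = list(names(modules$modules), colnames(z)))
  coverage <- stats::setNames(numeric(length(modules$modules)),
                              names(modules$modules))
  for (m in names(modules$modules)) {
    present <- intersect(modules$modules[[m]], rownames(z))
    coverage[m] <- length(present) / length(modules$modules[[m]])
    if (length(present) == 0) {
      iscape_warn("module %s has no feature in the dataset; scored NA", m)
      next
    }
    scores[m, ] <- colSums(z[present, , drop = FALSE])
  }
  structure(list(scores = scores,
                 module_ids = rownames(scores),
                 sample_ids = colnames(scores),
                 coverage = coverage,
                 scaling = list(center = attr(z, "center"),
                                scale = attr(z, "scale")),
                 study_id = stacked$study_id),
            class = "module_score_matrix")
}

# Mann-Whitney AUC with tie handling: P(case > control) + 0.5 P(tie),
# via midranks. Returns the AUC and the two-sided rank-sum p-value.
.auc_rank <- function(case, control) {
  n1 <- length(case)
  n2 <- length(control)
  r <- rank(c(case, control))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  p <- if (length(unique(c(case, control))) == 1) {
    1  # all tied: no evidence either way
  } else {
    suppressWarnings(stats::wilcox.test(case, control)$p.value)
  }
  list(auc = auc, p = p)
}

#' AUC of a score for case-vs-control discrimination
#'
#' AUC = P(score_case > score_control) + 0.5 P(tie) over all case-control
#' pairs (the Mann-Whitney identity); p from the two-sided rank-sum test.
#'
#' @param scores numeric vector, one score per sample.
#' @param labels vector of `"case"`/`"control"` aligned with `scores`.
#' @param module_id,study_id identifiers carried into the record.
#' @return an `auc_record`: list with `module_id`, `study_id`, `auc`, `p`,
#'   `n_case`, `n_control`.
#' @export
module_auc <- function(scores, labels, module_id = NA_character_,
                       study_id = NA_character_) {
  case <- scores[labels == "case"]
  control <- scores[labels == "control"]
  if (length(case) < 1 || length(control) < 1) {
    iscape_error("value_error", "need at least one case and one control")
  }
  r <- .auc_rank(case, control)
  structure(list(module_id = module_id, study_id = study_id,
                 auc = r$auc, p = r$p,
                 n_case = length(case), n_control = length(control)),
            class = "auc_record")
}

#' AUC records for every module of a score matrix
#'
#' @param msm a `module_score_matrix`.
#' @param labels `"case"`/`"control"` per sample (matrix column order).
#' @param study_id,disease,compartment identifiers carried into the rows.
#' @return data.frame of AUC records (one row per scored module).
#' @export
module_auc_table <- function(msm, labels, study_id = msm$study_id,
                             disease = NA_character_,
                             compartment = NA_character_) {
  rows <- lapply(msm$module_ids, function(m) {
    s <- msm$scores[m, ]
    if (all(is.na(s))) return(NULL)
    r <- module_auc(s, labels, module_id = m, study_id = study_id)
    data.frame(module_id = m, study_id = study_id, disease = disease,
               compartment = compartment, auc = r$auc, p = r$p,
               n_case = r$n_case, n_control = r$n_control,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Aggregate per-study AUCs into stability-weighted enrichment summaries
#'
#' Per (module, disease, compartment) group: mean AUC, SD across studies,
#' stability = 1/SD (capped at 1/0.01 to avoid infinities and flagged NA
#' when fewer than 2 studies contribute), and a Fisher-combined p over the
#' per-study rank-sum p-values (clipped below at 1e-300).
#'
#' @param records data.frame of AUC records (see [module_auc_table()]).
#' @return data.frame with one row per group: `module_id`, `disease`,
#'   `compartment`, `k_studies`, `mean_auc`, `sd_auc`, `stability`,
#'   `combined_p`.
#' @export
aggregate_module_auc <- function(records) {
  if (nrow(records) == 0) {
    iscape_error("value_error", "no AUC records to aggregate")
  }
  key <- interaction(records$module_id, records$disease,
                     records$compartment, drop = TRUE)
  rows <- lapply(split(records, key), function(d) {
    k <- nrow(d)
    sd_auc <- if (k >= 2) stats::sd(d$auc) else NA_real_
    stability <- if (k >= 2) 1 / max(sd_auc, 0.01) else NA_real_
    data.frame(module_id = d$module_id[1], disease = d$disease[1],
               compartment = d$compartment[1], k_studies = k,
               mean_auc = mean(d$auc), sd_auc = sd_auc,
               stability = stability,
               combined_p = fisher_combined_p(pmax(d$p, 1e-300)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Size-matched permutation test of one module's class effect
#'
#' The observed effect is the Hedges' g of the target module's aggregate
#' score between cases and controls. The null is built from `n_perm` random
#' modules of identical size drawn (without replacement within a draw) from
#' the features of the other modules, scored and contrasted the same way.
#' The observed effect is z-transformed against the null
#' (z = (effect - mean(null)) / sd(null)); p is the two-sided normal tail
#' of z, with the empirical two-sided tail reported alongside.
#' Deterministic given `seed`.
#'
#' @param target_module module id in `modules`.
#' @param modules a `module_set`.
#' @param features a `feature_matrix` or list of them.
#' @param labels `"case"`/`"control"` per sample.
#' @param n_perm number of random modules (>= 100).
#' @param seed integer seed.
#' @return list with `effect`, `z`, `p`, `p_empirical`, `null_effects`.
#' @export
permutation_module_test <- function(target_module, modules, features,
                                    labels, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) {
    iscape_error("value_error", "n_perm must be >= 100")
  }
  stacked <- if (inherits(features, "feature_matrix") &&
                 features$feature_type == "combined") {
    features
  } else {
    stack_features(features)
  }
  if (!target_module %in% names(modules$modules)) {
    iscape_error("lookup_error", "module '%s' not in the module set",
                 target_module)
  }
  z <- z_scale_rows(stacked$matrix)
  target <- intersect(modules$modules[[target_module]], rownames(z))
  size <- length(target)
  if (size == 0) {
    iscape_error("value_error", "target module has no feature present")
  }
  pool <- intersect(
    unlist(modules$modules[setdiff(names(modules$modules), target_module)],
           use.names = FALSE),
    rownames(z))
  if (length(pool) < size) {
    iscape_error("value_error",
                 "pool of other-module features (%d) smaller than the target module (%d)",
                 length(pool), size)
  }
  is_case <- labels == "case"
  score_effect <- function(feat) {
    s <- colSums(z[feat, , drop = FALSE])
    r <- .hedges_g_vec(mean(s[is_case]), stats::sd(s[is_case]),
                       sum(is_case),
                       mean(s[!is_case]), stats::sd(s[!is_case]),
                       sum(!is_case))
    r$g
  }
  effect <- score_effect(target)
  null_effects <- withr::with_seed(derive_seed(seed, 4L), {
    vapply(seq_len(n_perm), function(i) score_effect(sample(pool, size)),
           numeric(1))
  })
  z_stat <- (effect - mean(null_effects)) / stats::sd(null_effects)
  list(effect = effect,
       z = z_stat,
       p = 2 * stats::pnorm(-abs(z_stat)),
       p_empirical = (1 + sum(abs(null_effects) >= abs(effect))) /
         (1 + n_perm),
       null_effects = null_effects)
}

#' Predict treatment response from baseline module scores
#'
#' AUC of the score for responder status. The raw AUC treats responders as
#' the positive class; the directed AUC is max(auc, 1 - auc) with its
#' direction reported explicitly (a lower score in responders is flagged
#' rather than silently flipped).
#'
#' @param baseline_scores numeric vector, one score per patient.
#' @param response vector of `"responder"`/`"non_responder"`.
#' @return list with `auc` (raw), `directed_auc`, `direction`
#'   (`"higher_in_responders"` or `"lower_in_responders"`), `p`, `n_resp`,
#'   `n_nonresp`.
#' @export
predict_response <- function(baseline_scores, response) {
  resp <- baseline_scores[response == "responder"]
  nonresp <- baseline_scores[response == "non_responder"]
  if (length(resp) < 1 || length(nonresp) < 1) {
    iscape_error("value_error", "both response classes must be present")
  }
  r <- .auc_rank(resp, nonresp)
  list(auc = r$auc,
       directed_auc = max(r$auc, 1 - r$auc),
       direction = if (r$auc < 0.5) "lower_in_responders"
                   else "higher_in_responders",
       p = r$p,
       n_resp = length(resp),
       n_nonresp = length(nonresp))
}

#' Spearman correlation of module scores with disease severity
#'
#' Missing severity values are dropped pairwise; at least 4 complete pairs
#' are required.
#'
#' @param scores numeric vector of module scores.
#' @param severity numeric severity index (e.g. PASI), NA allowed.
#' @return list with `rho`, `p`, `n`.
#' @export
severity_correlation <- function(scores, severity) {
  ok <- !is.na(scores) & !is.na(severity)
  if (sum(ok) < 4) {
    iscape_error("insufficient_data_error",
                 "need >= 4 paired non-missing values (got %d)", sum(ok))
  }
  ct <- suppressWarnings(
    stats::cor.test(scores[ok], severity[ok], method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Two-sided rank-sum comparison of two score groups
#'
#' @param scores_a,scores_b numeric vectors (non-empty).
#' @return list with `statistic` (Mann-Whitney W) and `p`.
#' @export
compare_groups <- function(scores_a, scores_b) {
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    iscape_error("value_error", "both groups must be non-empty")
  }
  if (length(unique(c(scores_a, scores_b))) == 1) {
    return(list(statistic = length(scores_a) * length(scores_b) / 2, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(scores_a, scores_b))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
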