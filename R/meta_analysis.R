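# Random-effects meta-analysis of standardized mean differences.
#
# Per study, the case-control difference for a gene (or derived feature) is
# summarized as Hedges' g: the standardized mean difference
# SMD = (mean1 - mean2) / s_pooled corrected for small-sample upward bias
# by the factor 1 - 3/(4n - 9), n = n1 + n2. Across studies the pooled
# effect follows the random-effects model theta_k = mu + zeta_k + eps_k
# with between-study variance tau2 estimated by the DerSimonian-Laird
# moment method, study weights w*_k = 1/(se_k^2 + tau2), pooled estimate
# sum(w* g)/sum(w*) and SE sqrt(1/sum(w*)).

#' Hedges' g effect size for a two-group comparison
#'
#' @param mean1,sd1,n1 case-group mean, SD and size (n1 >= 2).
#' @param mean2,sd2,n2 control-group mean, SD and size (n2 >= 2).
#' @param study_id identifier carried into the record.
#' @return an `effect_size_record`: list with `study_id`, `g`, `se`, `n1`,
#'   `n2`. The SE evaluates the SMD standard-error formula
#'   sqrt((n1+n2)/(n1 n2) + g^2/(2(n1+n2))) at the bias-corrected g.
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2, study_id = "study") {
  if (n1 < 2 || n2 < 2) {
    iscape_error("value_error", "group sizes must be >= 2")
  }
  if (sd1 < 0 || sd2 < 0) {
    iscape_error("value_error", "standard deviations must be >= 0")
  }
  r <- .hedges_g_vec(mean1, sd1, n1, mean2, sd2, n2)
  if (is.na(r$g)) {
    iscape_error("degenerate_error",
                 "pooled SD is zero; effect size undefined")
  }
  structure(list(study_id = study_id, g = r$g, se = r$se,
                 n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "effect_size_record")
}

# Vectorized core: all arguments may be vectors/matrices of equal shape.
# Degenerate rows (zero pooled SD) yield NA rather than an error so the
# per-gene path can skip them.
.hedges_g_vec <- function(mean1, sd1, n1, mean2, sd2, n2) {
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  smd <- (mean1 - mean2) / s_pooled
  smd[s_pooled == 0] <- NA_real_
  n <- n1 + n2
  g <- smd * (1 - 3 / (4 * n - 9))
  se <- sqrt(n / (n1 * n2) + g^2 / (2 * n))
  list(g = g, se = se)
}

# Coerce a list of effect_size_records (or a data.frame with g/se columns)
# to a data.frame.
.as_effect_df <- function(effects) {
  if (is.data.frame(effects)) {
    stopifnot(all(c("g", "se") %in% colnames(effects)))
    return(effects)
  }
  do.call(rbind, lapply(effects, function(e) {
    data.frame(study_id = e$study_id %||% NA_character_, g = e$g, se = e$se,
               stringsAsFactors = FALSE)
  }))
}

#' DerSimonian-Laird estimate of between-study variance
#'
#' Moment estimator: with fixed-effect weights w = 1/se^2 and
#' Q = sum(w (g - g_FE)^2), tau2 = max(0, (Q - (k-1)) /
#' (sum(w) - sum(w^2)/sum(w))). A single study returns 0 with a warning
#' (heterogeneity is unidentifiable at k = 1).
#'
#' @param effects list of [hedges_g()] records, or a data.frame with
#'   columns `g` and `se`.
#' @return tau2 estimate (scalar, >= 0).
#' @export
dersimonian_laird_tau2 <- function(effects) {
  df <- .as_effect_df(effects)
  if (any(df$se <= 0)) {
    iscape_error("value_error", "all standard errors must be > 0")
  }
  if (nrow(df) < 2) {
    iscape_warn("tau2 requires >= 2 studies; returning 0 for k = %d",
                nrow(df))
    return(0)
  }
  .dl_tau2(df$g, df$se)
}

.dl_tau2 <- function(g, se) {
  w <- 1 / se^2
  gbar <- sum(w * g) / sum(w)
  q <- sum(w * (g - gbar)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (length(g) - 1)) / denom)
}

#' Pool effect sizes with a random-effects model
#'
#' Weights w*_k = 1/(se_k^2 + tau2) with tau2 from
#' [dersimonian_laird_tau2()]; pooled estimate sum(w* g)/sum(w*), SE
#' sqrt(1/sum(w*)), z = estimate/SE and a two-sided normal p-value.
#'
#' @param effects as in [dersimonian_laird_tau2()].
#' @param tau2 optional fixed tau2 (e.g. 0 for a fixed-effect fit);
#'   estimated when NULL.
#' @return a `pooled_effect`: list with `estimate`, `se`, `tau2`, `z`, `p`,
#'   `k` (and `fdr = NA`, filled by a correction pass across rows).
#' @export
pool_random_effects <- function(effects, tau2 = NULL) {
  df <- .as_effect_df(effects)
  if (nrow(df) == 0) {
    iscape_error("value_error", "cannot pool an empty set of effects")
  }
  if (any(df$se <= 0)) {
    iscape_error("value_error", "all standard errors must be > 0")
  }
  if (is.null(tau2)) {
    tau2 <- if (nrow(df) >= 2) .dl_tau2(df$g, df$se) else 0
  }
  w <- 1 / (df$se^2 + tau2)
  estimate <- sum(w * df$g) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- estimate / se
  structure(list(estimate = estimate, se = se, tau2 = tau2, z = z,
                 p = 2 * stats::pnorm(-abs(z)), fdr = NA_real_,
                 k = nrow(df)),
            class = "pooled_effect")
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues numeric vector in \[0, 1\] (NA allowed; propagated).
#' @return q-values, order-preserving with the input.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) {
    iscape_error("value_error", "p-values must lie in [0, 1]")
  }
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    q <- pmin(1, cummin(m / (m:1) * p[o]))
    out[ok][o] <- q
  }
  out
}

#' Fisher's method for combining independent p-values
#'
#' X2 = -2 sum(log p) referred to a chi-square distribution with 2m degrees
#' of freedom (upper tail).
#'
#' @param pvalues numeric vector in (0, 1].
#' @return combined p-value.
#' @export
fisher_combined_p <- function(pvalues) {
  if (length(pvalues) == 0) {
    iscape_error("value_error", "need at least one p-value")
  }
  if (any(pvalues <= 0 | pvalues > 1)) {
    iscape_error("value_error",
                 "p-values must lie in (0, 1]; clip zeros upstream")
  }
  stats::pchisq(-2 * sum(log(pvalues)), df = 2 * length(pvalues),
                lower.tail = FALSE)
}

#' Meta-analyze a study collection gene- or feature-wise
#'
#' For every row entity present in at least `min_studies` studies: Hedges'
#' g per study on the available rows, DerSimonian-Laird tau2, random-effects
#' pooling, then BH FDR across all rows of the stratum. Rows absent from a
#' study (or degenerate in it: zero pooled SD) are pooled over the studies
#' that carry them. Results do not depend on study order.
#'
#' @param collection a `study_collection` (assumed to be one
#'   disease/compartment stratum; no grouping is done here).
#' @param matrix_extractor function(study) returning the numeric rows x
#'   samples matrix to analyze; default uses the expression matrix.
#' @param min_studies minimum number of informative studies per row.
#' @param tau2 optional fixed tau2 passed through (NULL = estimate).
#' @return data.frame with columns `entity`, `estimate`, `se`, `tau2`, `z`,
#'   `p`, `fdr`, `k`, sorted by entity.
#' @export
meta_analyze <- function(collection, matrix_extractor = NULL,
                         min_studies = 1, tau2 = NULL) {
  extractor <- matrix_extractor %||% function(study) study$matrix
  studies <- collection$studies
  if (length(studies) == 0) {
    iscape_error("pipeline_error", "empty collection")
  }
  per_study <- lapply(studies, function(s) {
    m <- extractor(s)
    case <- m[, s$samples$class == "case", drop = FALSE]
    ctrl <- m[, s$samples$class == "control", drop = FALSE]
    if (ncol(case) < 2 || ncol(ctrl) < 2) {
      return(NULL)  # SE undefined; study contributes nothing
    }
    r <- .hedges_g_vec(rowMeans(case), row_sds(case), ncol(case),
                       rowMeans(ctrl), row_sds(ctrl), ncol(ctrl))
    data.frame(entity = rownames(m), g = r$g, se = r$se,
               stringsAsFactors = FALSE)
  })
  per_study <- Filter(Negate(is.null), per_study)
  entities <- sort(unique(unlist(lapply(per_study, `[[`, "entity"))))
  if (length(entities) == 0) {
    iscape_error("pipeline_error",
                 "no entity yields a usable effect in any study")
  }
  k_tot <- length(per_study)
  gm <- matrix(NA_real_, length(entities), k_tot,
               dimnames = list(entities, NULL))
  sm <- gm
  for (j in seq_len(k_tot)) {
    d <- per_study[[j]]
    gm[d$entity, j] <- d$g
    sm[d$entity, j] <- d$se
  }
  rows <- lapply(entities, function(e) {
    ok <- !is.na(gm[e, ]) & !is.na(sm[e, ])
    if (sum(ok) < max(1, min_studies)) return(NULL)
    pe <- pool_random_effects(data.frame(g = gm[e, ok], se = sm[e, ok]),
                              tau2 = tau2)
    data.frame(entity = e, estimate = pe$estimate, se = pe$se,
               tau2 = pe$tau2, z = pe$z, p = pe$p, k = pe$k,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    iscape_error("pipeline_error",
                 "no entity observed in >= %d studies", min_studies)
  }
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  out[, c("entity", "estimate", "se", "tau2", "z", "p", "fdr", "k")]
}
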