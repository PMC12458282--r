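# Synthetic multi-study generators. The generative model mirrors the
# random-effects model used downstream: the true standardized effect of
# study k for gene g is theta_kg = mu_g + zeta_kg with
# zeta_kg ~ N(0, tau2), and case means are shifted by theta_kg * noise_sd
# so the true Cohen's d equals theta_kg by construction.

#' Configuration for the synthetic study generator
#'
#' @param n_genes number of genes.
#' @param n_case,n_control group sizes (>= 2 each; standard errors are
#'   undefined below that).
#' @param true_effects per-gene true effect mu on the standardized
#'   (Cohen's d) scale; recycled to `n_genes`.
#' @param tau2 between-study variance of true effects (>= 0).
#' @param noise_sd within-group expression SD (> 0), log2 units.
#' @param baseline optional per-gene baseline log2 expression; drawn
#'   uniformly in \[4, 10\] from `seed` when omitted (typical microarray
#'   log-intensity range).
#' @param seed integer seed; all generators are pure functions of it.
#' @return a `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_genes, n_case, n_control,
                                   true_effects = 0, tau2 = 0, noise_sd = 1,
                                   baseline = NULL, seed = 1L) {
  if (n_case < 2 || n_control < 2) {
    iscape_error("config_error",
                 "n_case and n_control must be >= 2 (SE undefined below)")
  }
  if (tau2 < 0) iscape_error("config_error", "tau2 must be >= 0")
  if (noise_sd <= 0) iscape_error("config_error", "noise_sd must be > 0")
  true_effects <- rep_len(true_effects, n_genes)
  if (is.null(baseline)) {
    baseline <- withr::with_seed(derive_seed(seed, 0L),
                                 stats::runif(n_genes, 4, 10))
  }
  baseline <- rep_len(baseline, n_genes)
  structure(list(n_genes = n_genes, n_case = n_case, n_control = n_control,
                 true_effects = true_effects, tau2 = tau2,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "synthetic_study_config")
}

#' Generate one synthetic case-control study
#'
#' Controls are drawn from N(baseline_g, noise_sd^2); cases from
#' N(baseline_g + theta_kg * noise_sd, noise_sd^2) where
#' theta_kg = mu_g + zeta_kg and zeta_kg ~ N(0, tau2). Values are truncated
#' at 0 (synthetic data are generated directly on the log2 scale).
#' Deterministic given (config$seed, study_index).
#'
#' @param config a [synthetic_study_config()].
#' @param study_index integer >= 1, selects the deterministic substream.
#' @param n_case,n_control optional overrides of the config sizes.
#' @param disease,compartment metadata fields for the generated samples.
#' @return an `expression_study`; the per-gene true effects used are in
#'   `attr(, "theta")`.
#' @export
generate_study <- function(config, study_index, n_case = config$n_case,
                           n_control = config$n_control,
                           disease = "disease_A", compartment = "blood") {
  if (n_case < 2 || n_control < 2) {
    iscape_error("config_error", "group sizes must be >= 2")
  }
  g <- config$n_genes
  sid <- sprintf("%s_%s_study%02d", disease, compartment, study_index)
  out <- withr::with_seed(derive_seed(config$seed, study_index), {
    zeta <- if (config$tau2 > 0) {
      stats::rnorm(g, 0, sqrt(config$tau2))
    } else {
      numeric(g)
    }
    theta <- config$true_effects + zeta
    n <- n_case + n_control
    noise <- matrix(stats::rnorm(g * n, 0, config$noise_sd), g, n)
    m <- config$baseline + noise
    m[, seq_len(n_case)] <- m[, seq_len(n_case)] + theta * config$noise_sd
    list(m = pmax(m, 0), theta = theta)
  })
  m <- out$m
  rownames(m) <- sprintf("gene%04d", seq_len(g))
  classes <- c(rep("case", n_case), rep("control", n_control))
  meta <- data.frame(
    sample_id = sprintf("%s_s%03d", sid, seq_len(n_case + n_control)),
    study_id = sid, disease = disease, class = classes,
    compartment = compartment, stringsAsFactors = FALSE)
  colnames(m) <- meta$sample_id
  study <- expression_study(sid, m, meta, platform = "microarray",
                            log_scale = TRUE)
  attr(study, "theta") <- out$theta
  study
}

#' Generate a multi-study collection sharing mu and tau2
#'
#' Studies share the configured per-gene mean effects and heterogeneity but
#' draw independent study-level deviations zeta. Group sizes are jittered
#' by up to `size_jitter` (fraction, default 0.2) deterministically per
#' study.
#'
#' @param config a [synthetic_study_config()].
#' @param n_studies number of studies (>= 1).
#' @param disease,compartment stratum labels.
#' @param size_jitter fractional jitter of the group sizes in \[0, 1).
#' @param study_offset added to the per-study index (use to make strata
#'   within one collection draw distinct substreams).
#' @return a `study_collection`.
#' @export
generate_collection <- function(config, n_studies, disease = "disease_A",
                                compartment = "blood", size_jitter = 0.2,
                                study_offset = 0L) {
  if (n_studies < 1) {
    iscape_error("config_error", "n_studies must be >= 1")
  }
  studies <- lapply(seq_len(n_studies), function(i) {
    idx <- i + study_offset
    jit <- withr::with_seed(derive_seed(config$seed, 10000L + idx),
                            stats::runif(2, 1 - size_jitter, 1 + size_jitter))
    n_case <- max(2L, as.integer(round(config$n_case * jit[1])))
    n_control <- max(2L, as.integer(round(config$n_control * jit[2])))
    generate_study(config, idx, n_case = n_case, n_control = n_control,
                   disease = disease, compartment = compartment)
  })
  study_collection(studies)
}

#' Configuration for the planted feature-landscape generator
#'
#' @param n_features number of features.
#' @param n_diseases number of diseases (>= 4; rank correlations need
#'   points).
#' @param module_assignment integer module id per feature, contiguous from
#'   1; default splits the features evenly into `n_modules`.
#' @param n_modules used only when `module_assignment` is NULL.
#' @param within_module_correlation target Pearson correlation in \[0, 1\]
#'   between features of the same module.
#' @param seed integer seed.
#' @return a `synthetic_landscape_config`.
#' @export
synthetic_landscape_config <- function(n_features, n_diseases,
                                       module_assignment = NULL,
                                       n_modules = 15,
                                       within_module_correlation = 0.9,
                                       seed = 1L) {
  if (n_diseases < 4) {
    iscape_error("config_error", "n_diseases must be >= 4")
  }
  if (within_module_correlation < 0 || within_module_correlation > 1) {
    iscape_error("config_error",
                 "within_module_correlation must be in [0, 1]")
  }
  if (is.null(module_assignment)) {
    module_assignment <- rep_len(seq_len(n_modules), n_features)
    module_assignment <- sort(module_assignment)
  }
  if (length(module_assignment) != n_features ||
      !identical(sort(unique(module_assignment)),
                 seq_len(max(module_assignment)))) {
    iscape_error("config_error",
                 "module ids must be contiguous from 1, one per feature")
  }
  structure(list(n_features = n_features, n_diseases = n_diseases,
                 module_assignment = module_assignment,
                 within_module_correlation = within_module_correlation,
                 seed = as.integer(seed)),
            class = "synthetic_landscape_config")
}

#' Generate a feature landscape with planted modules
#'
#' Each module m has a latent per-disease profile z_m ~ N(0, 1); feature f
#' in module m has effect profile
#' sqrt(rho) * z_m + sqrt(1 - rho) * e_f with independent e_f ~ N(0, 1),
#' so any two features of the same module have correlation rho and features
#' of different modules are independent. The FDR matrix is set to 0.01 so
#' every feature passes the significance filter. Ground truth is in
#' `attr(, "module_assignment")`.
#'
#' @param config a [synthetic_landscape_config()].
#' @return a `feature_landscape` (see [build_landscape()]).
#' @export
generate_planted_landscape <- function(config) {
  rho <- config$within_module_correlation
  n_mod <- max(config$module_assignment)
  eff <- withr::with_seed(derive_seed(config$seed, 1L), {
    z <- matrix(stats::rnorm(n_mod * config$n_diseases),
                n_mod, config$n_diseases)
    e <- matrix(stats::rnorm(config$n_features * config$n_diseases),
                config$n_features, config$n_diseases)
    sqrt(rho) * z[config$module_assignment, , drop = FALSE] +
      sqrt(1 - rho) * e
  })
  rownames(eff) <- sprintf("feature%04d", seq_len(config$n_features))
  colnames(eff) <- sprintf("disease%02d", seq_len(config$n_diseases))
  fdr <- matrix(0.01, nrow(eff), ncol(eff), dimnames = dimnames(eff))
  out <- new_feature_landscape(
    effect = eff, fdr = fdr,
    feature_type = rep("feature", nrow(eff)),
    compartment = "blood")
  attr(out, "module_assignment") <- config$module_assignment
  out
}

#' Generate a cell-mixture study with known proportions
#'
#' Sample expression (linear scale) is `basis %*% proportions[, j]` plus
#' N(0, noise_sd^2) noise truncated at 0. The true proportions are stored
#' in `attr(, "true_proportions")`.
#'
#' @param basis a [basis_matrix()].
#' @param proportions celltypes x samples matrix; columns non-negative and
#'   summing to 1 within 1e-6.
#' @param noise_sd additive noise SD (>= 0), linear-expression units.
#' @param seed integer seed.
#' @return an `expression_study` with `log_scale = FALSE` (classes are
#'   assigned round-robin; they carry no signal).
#' @export
generate_mixture_study <- function(basis, proportions, noise_sd = 0,
                                   seed = 1L) {
  if (nrow(proportions) != length(basis$celltype_names)) {
    iscape_error("config_error",
                 "proportions must have one row per basis cell type")
  }
  if (any(proportions < 0) || any(abs(colSums(proportions) - 1) > 1e-6)) {
    iscape_error("config_error",
                 "proportion columns must be non-negative and sum to 1")
  }
  n <- ncol(proportions)
  if (n < 2) iscape_error("config_error", "need at least 2 samples")
  m <- basis$matrix %*% proportions
  if (noise_sd > 0) {
    m <- m + withr::with_seed(derive_seed(seed, 2L),
                              matrix(stats::rnorm(length(m), 0, noise_sd),
                                     nrow(m), ncol(m)))
    m <- pmax(m, 0)
  }
  meta <- data.frame(
    sample_id = sprintf("mix_s%03d", seq_len(n)),
    study_id = "mixture_study", disease = "mixture", class =
      rep(c("control", "case"), length.out = n),
    compartment = "blood", stringsAsFactors = FALSE)
  colnames(m) <- meta$sample_id
  study <- expression_study("mixture_study", m, meta, platform = "rnaseq",
                            log_scale = FALSE)
  attr(study, "true_proportions") <- proportions
  study
}
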