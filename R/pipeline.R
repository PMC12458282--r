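# End-to-end orchestration on synthetic multi-study collections: simulate
# -> harmonize/filter -> featurize -> meta-analyze (genes and features) ->
# landscape -> modules -> scores -> validation -> enrichment, with
# per-stage TSV/JSON artifacts, a manifest, deterministic seeding and
# optional stage caching.

PIPELINE_REQUIRED_FIELDS <- c(
  "n_diseases", "n_studies_per_disease", "n_case", "n_control", "n_genes",
  "n_signal_genes", "effect_size", "tau2", "noise_sd",
  "n_pathway_sets", "n_tf_sets", "n_mirna_sets", "set_size",
  "n_celltypes", "cytokine_panel_size",
  "alpha", "min_overlap", "min_patients",
  "fdr_threshold", "min_studies",
  "k_modules", "linkage", "n_perturbations", "n_null",
  "n_perm")

#' Default synthetic pipeline configuration
#'
#' The defaults describe a desk-scale analogue of a multi-disease blood
#' compendium: 10 diseases, 3 studies each, 40 subjects per study, 500
#' genes of which 50 carry a planted standardized effect shared across
#' diseases with disease-specific strength, and moderate between-study
#' heterogeneity.
#'
#' @param ... overrides of any config field.
#' @return named list validated by [validate_pipeline_config()].
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    n_diseases = 10, n_studies_per_disease = 3,
    n_case = 20, n_control = 20,
    n_genes = 500, n_signal_genes = 50, effect_size = 1,
    tau2 = 0.05, noise_sd = 1,
    n_pathway_sets = 20, n_tf_sets = 10, n_mirna_sets = 10, set_size = 25,
    n_celltypes = 6, cytokine_panel_size = 30,
    alpha = 0.25, min_overlap = 5, min_patients = 4,
    fdr_threshold = 0.05, min_studies = 1,
    k_modules = 6, linkage = "ward.D2",
    n_perturbations = 30, n_null = 20, do_robustness = TRUE,
    n_perm = 200)
  over <- list(...)
  cfg[names(over)] <- over
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks field presence and basic numeric sanity before any stage runs.
#'
#' @param config named list (e.g. parsed from JSON).
#' @return the config, invisibly usable, after validation.
#' @export
validate_pipeline_config <- function(config) {
  missing <- setdiff(PIPELINE_REQUIRED_FIELDS, names(config))
  if (length(missing) > 0) {
    iscape_error("schema_error", "config missing required field(s): %s",
                 paste(missing, collapse = ", "))
  }
  num <- setdiff(PIPELINE_REQUIRED_FIELDS, "linkage")
  bad <- num[!vapply(config[num],
                     function(v) is.numeric(v) && length(v) == 1 && v >= 0,
                     logical(1))]
  if (length(bad) > 0) {
    iscape_error("schema_error", "non-numeric/negative config field(s): %s",
                 paste(bad, collapse = ", "))
  }
  if (config$n_signal_genes > config$n_genes) {
    iscape_error("schema_error", "n_signal_genes exceeds n_genes")
  }
  config
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with config fields (missing fields are an error).
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

# --- synthetic world builders ------------------------------------------

# Gene-set collections for the synthetic pipeline: a few sets loaded with
# planted signal genes (so derived features carry case-control signal),
# the rest random.
.synthetic_gene_sets <- function(cfg, seed) {
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  signal <- genes[seq_len(cfg$n_signal_genes)]
  mk <- function(n_sets, n_signal_sets, prefix, category, offset) {
    withr::with_seed(derive_seed(seed, offset), {
      sets <- lapply(seq_len(n_sets), function(i) {
        if (i <= n_signal_sets) {
          c(sample(signal, min(cfg$set_size %/% 2, length(signal))),
            sample(setdiff(genes, signal),
                   cfg$set_size - min(cfg$set_size %/% 2, length(signal))))
        } else {
          sample(genes, cfg$set_size)
        }
      })
      names(sets) <- sprintf("%s_%02d", prefix, seq_len(n_sets))
      gene_set_collection(sets, category)
    })
  }
  list(pathway = mk(cfg$n_pathway_sets, max(1, cfg$n_pathway_sets %/% 4),
                    "PATHWAY", "pathway", 101L),
       tf_regulon = mk(cfg$n_tf_sets, max(1, cfg$n_tf_sets %/% 5),
                       "TF", "tf_regulon", 102L),
       mirna_targets = mk(cfg$n_mirna_sets, max(1, cfg$n_mirna_sets %/% 5),
                          "MIR", "mirna_targets", 103L))
}

# Marker-structured basis matrix over the first genes of the universe.
.synthetic_basis <- function(cfg, seed) {
  n_basis_genes <- min(cfg$n_genes, 40 * cfg$n_celltypes)
  genes <- sprintf("gene%04d", seq_len(n_basis_genes))
  withr::with_seed(derive_seed(seed, 104L), {
    m <- matrix(stats::runif(n_basis_genes * cfg$n_celltypes, 5, 50),
                n_basis_genes, cfg$n_celltypes,
                dimnames = list(genes,
                                sprintf("celltype%02d",
                                        seq_len(cfg$n_celltypes))))
    marker_block <- n_basis_genes %/% cfg$n_celltypes
    for (ct in seq_len(cfg$n_celltypes)) {
      idx <- ((ct - 1) * marker_block + 1):(ct * marker_block)
      m[idx, ct] <- m[idx, ct] * 10
    }
    basis_matrix(m)
  })
}

# Per-disease case-control collections sharing a planted signal with
# disease-specific strength, plus optional response/severity metadata.
.simulate_collections <- function(cfg, seed) {
  genes_signal <- seq_len(cfg$n_signal_genes)
  diseases <- sprintf("disease%02d", seq_len(cfg$n_diseases))
  strength <- withr::with_seed(derive_seed(seed, 105L),
                               stats::runif(cfg$n_diseases, 0.5, 1.5))
  collections <- list()
  for (d in seq_len(cfg$n_diseases)) {
    mu <- numeric(cfg$n_genes)
    mu[genes_signal] <- cfg$effect_size * strength[d]
    sc <- synthetic_study_config(
      n_genes = cfg$n_genes, n_case = cfg$n_case,
      n_control = cfg$n_control, true_effects = mu, tau2 = cfg$tau2,
      noise_sd = cfg$noise_sd, seed = derive_seed(seed, 200L + d))
    coll <- generate_collection(sc, cfg$n_studies_per_disease,
                                disease = diseases[d], compartment = "blood")
    coll$studies <- lapply(seq_along(coll$studies), function(i) {
      s <- coll$studies[[i]]
      n <- nrow(s$samples)
      extra <- withr::with_seed(
        derive_seed(seed, 300L + d * 100L + i), {
          list(response = ifelse(stats::runif(n) < 0.5, "responder",
                                 "non_responder"),
               severity = round(stats::runif(n, 0, 72), 1))
        })
      s$samples$response <- extra$response
      s$samples$severity <- extra$severity
      s
    })
    collections[[diseases[d]]] <- study_collection(unname(coll$studies))
  }
  collections
}

# --- stage plumbing -----------------------------------------------------

.stage <- function(name, outdir, resume, fn) {
  cache <- file.path(outdir, "cache", paste0(name, ".rds"))
  if (resume && file.exists(cache)) {
    message(sprintf("[%s] resumed from cache", name))
    return(readRDS(cache))
  }
  message(sprintf("[%s] running", name))
  res <- tryCatch(fn(), error = function(e) {
    report <- list(stage = name, error = conditionMessage(e),
                   class = class(e))
    jsonlite::write_json(report, file.path(outdir, "error.json"),
                         auto_unbox = TRUE)
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("pipeline_error", "immunoscape_error")))
  })
  dir.create(dirname(cache), recursive = TRUE, showWarnings = FALSE)
  saveRDS(res, cache)
  res
}

#' Run the full synthetic pipeline
#'
#' Stages run in order (simulate -> harmonize/filter -> featurize ->
#' meta-analyze genes and features -> landscape -> modules -> scores ->
#' validation -> enrichment); each writes TSV/JSON artifacts under
#' `outdir` plus a manifest recording the package version, seed and
#' parameters. Numeric artifacts are byte-identical across re-runs with the
#' same config and seed. With `resume = TRUE`, stages whose cached result
#' exists under `outdir/cache` are skipped.
#'
#' @param config list from [default_pipeline_config()] /
#'   [read_pipeline_config()].
#' @param seed integer master seed for every source of randomness.
#' @param outdir artifact directory (created).
#' @param resume reuse cached stage results if present.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1L,
                         outdir = "pipeline_out", resume = FALSE) {
  config <- validate_pipeline_config(config)
  seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # 01 simulate
  sim <- .stage("01_simulate", outdir, resume, function() {
    collections <- .simulate_collections(config, seed)
    sets <- .synthetic_gene_sets(config, seed)
    basis <- .synthetic_basis(config, seed)
    panel <- withr::with_seed(
      derive_seed(seed, 106L),
      c(sprintf("gene%04d", seq_len(min(10, config$n_signal_genes))),
        sample(sprintf("gene%04d",
                       (config$n_signal_genes + 1):config$n_genes),
               config$cytokine_panel_size -
                 min(10, config$n_signal_genes))))
    d <- file.path(outdir, "01_simulate")
    dir.create(d, showWarnings = FALSE)
    for (nm in names(sets)) {
      write_gene_sets(sets[[nm]], file.path(d, paste0(nm, ".gmt")))
    }
    write_tsv_matrix(basis$matrix, file.path(d, "basis.tsv"),
                     id_col = "gene_id")
    writeLines(panel, file.path(d, "cytokine_panel.txt"))
    list(collections = collections, sets = sets, basis = basis,
         panel = panel)
  })

  # 02 harmonize + filter
  filtered <- .stage("02_filter", outdir, resume, function() {
    out <- lapply(sim$collections, function(coll) {
      coll$studies <- lapply(coll$studies, harmonize_study)
      filter_collection(study_collection(unname(coll$studies)),
                        min_patients = config$min_patients)
    })
    d <- file.path(outdir, "02_filter")
    dir.create(d, showWarnings = FALSE)
    strata <- do.call(rbind, lapply(out, `[[`, "strata"))
    write_tsv_table(strata, file.path(d, "strata.tsv"))
    out
  })

  # 03 featurize
  feats <- .stage("03_featurize", outdir, resume, function() {
    d <- file.path(outdir, "03_featurize")
    dir.create(d, showWarnings = FALSE)
    out <- lapply(filtered, function(coll) {
      lapply(coll$studies, function(s) {
        fam <- featurize_study(s, sets_by_category = sim$sets,
                               basis = sim$basis, panel = sim$panel,
                               alpha = config$alpha,
                               min_overlap = config$min_overlap)
        stacked <- stack_features(fam)
        write_tsv_matrix(stacked$matrix,
                         file.path(d, paste0(s$study_id, ".tsv")),
                         id_col = "feature_id")
        jsonlite::write_json(
          list(study_id = s$study_id,
               feature_type = attr(stacked, "row_type"),
               params = list(alpha = config$alpha,
                             min_overlap = config$min_overlap),
               dropped_sets = unlist(lapply(fam, attr, "dropped_sets"))),
          file.path(d, paste0(s$study_id, ".json")),
          auto_unbox = TRUE, digits = NA)
        stacked
      })
    })
    out
  })

  # 04 meta-analysis: genes and features, per disease
  meta <- .stage("04_meta", outdir, resume, function() {
    d <- file.path(outdir, "04_meta")
    dir.create(d, showWarnings = FALSE)
    gene_tables <- list()
    feature_tables <- list()
    for (disease in names(filtered)) {
      coll <- filtered[[disease]]
      gene_tables[[disease]] <- meta_analyze(
        coll, min_studies = config$min_studies)
      fstudies <- lapply(names(coll$studies), function(sid) {
        list(matrix = feats[[disease]][[sid]]$matrix,
             samples = coll$studies[[sid]]$samples)
      })
      feature_tables[[disease]] <- meta_analyze(
        list(studies = fstudies), min_studies = config$min_studies)
      write_tsv_table(gene_tables[[disease]],
                      file.path(d, paste0("genes_", disease, ".tsv")))
      write_tsv_table(feature_tables[[disease]],
                      file.path(d, paste0("features_", disease, ".tsv")))
    }
    list(genes = gene_tables, features = feature_tables)
  })

  # 05 landscape
  land <- .stage("05_landscape", outdir, resume, function() {
    full <- build_landscape(meta$features, compartment = "blood")
    full$feature_type <- sub(":.*$", "", full$feature_ids)
    sig <- significant_features(full, threshold = config$fdr_threshold)
    write_landscape(sig, file.path(outdir, "05_landscape"))
    list(full = full, significant = sig)
  })

  # 06 modules
  modules <- .stage("06_modules", outdir, resume, function() {
    corr <- feature_correlation_matrix(land$significant)
    ms <- cluster_features(corr, k = config$k_modules,
                           linkage = config$linkage)
    d <- file.path(outdir, "06_modules")
    write_module_set(ms, d)
    write_tsv_matrix(corr, file.path(d, "correlation.tsv"),
                     id_col = "feature_id")
    robustness <- NULL
    if (isTRUE(config$do_robustness)) {
      robustness <- cluster_number_robustness(
        land$significant, k = config$k_modules,
        n_perturbations = config$n_perturbations,
        n_null = config$n_null, linkage = config$linkage,
        seed = derive_seed(seed, 400L))
      jsonlite::write_json(
        robustness[c("stability", "p")],
        file.path(d, "robustness.json"), auto_unbox = TRUE, digits = NA)
    }
    list(modules = ms, corr = corr, robustness = robustness)
  })

  # 07 module scores
  scores <- .stage("07_scores", outdir, resume, function() {
    d <- file.path(outdir, "07_scores")
    dir.create(d, showWarnings = FALSE)
    out <- lapply(names(filtered), function(disease) {
      lapply(names(filtered[[disease]]$studies), function(sid) {
        msm <- module_scores(feats[[disease]][[sid]], modules$modules)
        write_tsv_matrix(msm$scores, file.path(d, paste0(sid, ".tsv")),
                         id_col = "module_id")
        msm
      })
    })
    names(out) <- names(filtered)
    for (disease in names(filtered)) {
      names(out[[disease]]) <- names(filtered[[disease]]$studies)
    }
    out
  })

  # 08 validation: AUC enrichment, permutation test, response, severity
  validation <- .stage("08_validate", outdir, resume, function() {
    d <- file.path(outdir, "08_validate")
    dir.create(d, showWarnings = FALSE)
    auc_rows <- list()
    for (disease in names(filtered)) {
      for (sid in names(filtered[[disease]]$studies)) {
        auc_rows[[paste(disease, sid)]] <- module_auc_table(
          scores[[disease]][[sid]],
          filtered[[disease]]$studies[[sid]]$samples$class,
          study_id = sid, disease = disease, compartment = "blood")
      }
    }
    auc_records <- do.call(rbind, auc_rows)
    rownames(auc_records) <- NULL
    summaries <- aggregate_module_auc(auc_records)
    write_tsv_table(auc_records, file.path(d, "auc_records.tsv"))
    write_tsv_table(summaries, file.path(d, "auc_summaries.tsv"))

    # permutation-validate the strongest-effect module for which a
    # size-matched null is drawable (pool of other-module features >= size)
    sig <- land$significant
    mean_eff <- vapply(modules$modules$modules, function(f) {
      mean(abs(sig$effect[f, ]), na.rm = TRUE)
    }, numeric(1))
    sizes <- lengths(modules$modules$modules)
    feasible <- sizes <= sum(sizes) - sizes
    if (!any(feasible)) {
      iscape_error("value_error",
                   "no module admits a size-matched permutation null")
    }
    target <- names(which.max(mean_eff[feasible]))
    d1 <- names(filtered)[1]
    s1 <- names(filtered[[d1]]$studies)[1]
    perm <- permutation_module_test(
      target, modules$modules, feats[[d1]][[s1]],
      filtered[[d1]]$studies[[s1]]$samples$class,
      n_perm = config$n_perm, seed = derive_seed(seed, 500L))
    jsonlite::write_json(
      c(list(target_module = target, n_perm = config$n_perm,
             seed = derive_seed(seed, 500L)),
        perm[c("effect", "z", "p", "p_empirical")]),
      file.path(d, "permutation_test.json"), auto_unbox = TRUE, digits = NA)

    # treatment response and severity on the same study's metadata
    meta1 <- filtered[[d1]]$studies[[s1]]$samples
    sc1 <- scores[[d1]][[s1]]$scores[target, ]
    resp <- predict_response(sc1, meta1$response)
    sev <- severity_correlation(sc1, meta1$severity)
    jsonlite::write_json(
      list(module = target, study = s1,
           response_auc = resp[c("auc", "directed_auc", "direction", "p")],
           severity = sev),
      file.path(d, "clinical_validation.json"), auto_unbox = TRUE,
      digits = NA)
    list(auc_records = auc_records, summaries = summaries, perm = perm,
         target_module = target, response = resp, severity = sev)
  })

  # 09 enrichment of up-regulated genes in the first disease
  enrich <- .stage("09_enrich", outdir, resume, function() {
    d1 <- names(meta$genes)[1]
    tb <- meta$genes[[d1]]
    query <- tb$entity[tb$fdr < config$fdr_threshold & tb$estimate > 0]
    res <- if (length(query) > 0) {
      hypergeometric_enrichment(query, tb$entity, sim$sets$pathway)
    } else {
      data.frame()
    }
    d <- file.path(outdir, "09_enrich")
    dir.create(d, showWarnings = FALSE)
    write_tsv_table(res, file.path(d, paste0("ora_up_", d1, ".tsv")))
    res
  })

  manifest <- list(package = "immunoscape",
                   version = as.character(utils::packageVersion("immunoscape")),
                   seed = seed,
                   config = config,
                   stages = sprintf("0%d_%s", 1:9,
                                    c("simulate", "filter", "featurize",
                                      "meta", "landscape", "modules",
                                      "scores", "validate", "enrich")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(collections = filtered, meta = meta, landscape = land,
                 modules = modules, scores = scores,
                 validation = validation, enrichment = enrich,
                 manifest = manifest))
}
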