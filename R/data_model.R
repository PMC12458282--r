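# Shared data types, standard file formats, harmonization and inclusion
# filters for multi-study case-control expression collections.

REQUIRED_METADATA_COLS <- c("sample_id", "study_id", "disease", "class",
                            "compartment")
OPTIONAL_METADATA_COLS <- c("tissue_name", "timepoint", "treated",
                            "response", "severity")

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `study_id`, `disease`, `class`
#' (`case`/`control`), `compartment` (`blood`/`tissue`). Optional columns:
#' `tissue_name`, `timepoint`, `treated` (logical), `response`
#' (`responder`/`non_responder`), `severity` (finite numeric, clinical-index
#' units such as PASI).
#'
#' @param metadata data.frame, one row per sample.
#' @return the metadata, invisibly, after validation.
#' @export
validate_sample_metadata <- function(metadata) {
  missing <- setdiff(REQUIRED_METADATA_COLS, colnames(metadata))
  if (length(missing) > 0) {
    iscape_error("schema_error",
                 "metadata is missing required column(s): %s",
                 paste(missing, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) {
    iscape_error("schema_error", "sample_id values must be unique")
  }
  bad_class <- setdiff(unique(metadata$class), c("case", "control"))
  if (length(bad_class) > 0) {
    iscape_error("schema_error",
                 "class must be 'case' or 'control'; found: %s",
                 paste(bad_class, collapse = ", "))
  }
  bad_comp <- setdiff(unique(metadata$compartment), c("blood", "tissue"))
  if (length(bad_comp) > 0) {
    iscape_error("schema_error",
                 "compartment must be 'blood' or 'tissue'; found: %s",
                 paste(bad_comp, collapse = ", "))
  }
  if ("severity" %in% colnames(metadata)) {
    sev <- metadata$severity
    if (any(!is.na(sev) & !is.finite(sev))) {
      iscape_error("schema_error", "severity values must be finite")
    }
  }
  invisible(metadata)
}

#' Construct an expression study
#'
#' An expression study is one case-control dataset: a genes x samples
#' matrix (log-scale unless stated otherwise) plus per-sample metadata.
#'
#' @param study_id character scalar.
#' @param matrix numeric genes x samples matrix with gene ids as rownames
#'   and sample ids as colnames.
#' @param samples sample metadata data.frame (see
#'   [validate_sample_metadata()]); row order must match matrix columns.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param log_scale logical; whether values are on the log2 scale.
#' @return object of class `expression_study`.
#' @export
expression_study <- function(study_id, matrix, samples,
                             platform = c("microarray", "rnaseq"),
                             log_scale = TRUE) {
  platform <- match.arg(platform)
  validate_sample_metadata(samples)
  if (ncol(matrix) != nrow(samples)) {
    iscape_error("consistency_error",
                 "study %s: %d matrix columns but %d metadata rows",
                 study_id, ncol(matrix), nrow(samples))
  }
  if (is.null(rownames(matrix))) {
    iscape_error("schema_error", "expression matrix must have gene rownames")
  }
  if (anyDuplicated(rownames(matrix))) {
    iscape_error("schema_error", "gene ids must be unique")
  }
  if (is.null(colnames(matrix))) colnames(matrix) <- samples$sample_id
  if (!identical(colnames(matrix), as.character(samples$sample_id))) {
    iscape_error("consistency_error",
                 "study %s: matrix column names do not match sample_id order",
                 study_id)
  }
  if (!all(is.finite(matrix))) {
    iscape_error("value_error", "study %s: non-finite expression values",
                 study_id)
  }
  if (length(unique(samples$class)) < 2) {
    iscape_error("consistency_error",
                 "study %s needs at least one case and one control", study_id)
  }
  structure(list(study_id = study_id,
                 matrix = matrix,
                 gene_ids = rownames(matrix),
                 samples = samples,
                 platform = platform,
                 log_scale = log_scale),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d genes x %d samples (%s, %s)\n",
              x$study_id, nrow(x$matrix), ncol(x$matrix), x$platform,
              if (x$log_scale) "log2" else "linear"))
  invisible(x)
}

#' Load an expression study from TSV files
#'
#' The matrix file is tab-delimited, genes in rows, first column the gene
#' id, header = sample ids. The metadata file (TSV) has one row per sample
#' with the required columns. Duplicate gene rows are collapsed by mean;
#' matrix columns are reordered to match metadata rows.
#'
#' @param matrix_path,metadata_path file paths.
#' @param platform,log_scale see [expression_study()].
#' @return an `expression_study`.
#' @export
load_expression_study <- function(matrix_path, metadata_path,
                                  platform = "microarray", log_scale = TRUE) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  gene <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(gene)) {
    # collapse duplicate gene rows by mean (rowsum orders rows by group)
    ms <- rowsum(m, gene)
    cnt <- table(gene)
    m <- ms / as.vector(cnt[rownames(ms)])
    m <- m[match(unique(gene), rownames(m)), , drop = FALSE]
  } else {
    rownames(m) <- gene
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
  missing <- setdiff(meta$sample_id, colnames(m))
  if (length(missing) > 0) {
    iscape_error("consistency_error",
                 "samples in metadata but not in matrix header: %s",
                 paste(missing, collapse = ", "))
  }
  m <- m[, as.character(meta$sample_id), drop = FALSE]
  expression_study(unique(meta$study_id)[1], m, meta,
                   platform = platform, log_scale = log_scale)
}

#' Write an expression study to TSV files
#'
#' Inverse of [load_expression_study()]; values round-trip to at least six
#' decimals.
#'
#' @param study an `expression_study`.
#' @param matrix_path,metadata_path output file paths.
#' @return invisibly, the matrix path.
#' @export
write_expression_study <- function(study, matrix_path, metadata_path) {
  write_tsv_matrix(study$matrix, matrix_path, id_col = "gene_id")
  write_tsv_table(study$samples, metadata_path)
  invisible(matrix_path)
}

#' Harmonize a study to the log2 scale
#'
#' Raw RNA-seq counts are converted to TPM (gene length normalization, then
#' per-sample scaling to one million) and log2(x+1)-transformed. Data that
#' are already normalized are log2(x+1)-transformed only when they look
#' linear-scale: the maximum value exceeds `log_max_threshold` (default 50,
#' a standard heuristic; log2 expression essentially never exceeds ~30).
#' The operation is idempotent on its own output.
#'
#' @param study an `expression_study`.
#' @param counts_are_raw logical; treat the matrix as raw counts.
#' @param gene_lengths numeric vector of gene lengths in bases, named by
#'   gene id (required when `counts_are_raw`).
#' @param log_max_threshold numeric, log-detection heuristic threshold.
#' @return the harmonized `expression_study` (flagged `log_scale = TRUE`).
#' @export
harmonize_study <- function(study, counts_are_raw = FALSE,
                            gene_lengths = NULL, log_max_threshold = 50) {
  m <- study$matrix
  if (counts_are_raw) {
    if (any(m < 0)) {
      iscape_error("value_error", "raw counts must be non-negative")
    }
    if (is.null(gene_lengths)) {
      iscape_error("value_error",
                   "gene_lengths are required for TPM normalization")
    }
    len_kb <- gene_lengths[study$gene_ids] / 1000
    if (any(is.na(len_kb) | len_kb <= 0)) {
      iscape_error("value_error",
                   "every gene needs a positive length for TPM")
    }
    rate <- m / len_kb
    denom <- colSums(rate)
    denom[denom == 0] <- 1  # all-zero sample stays all-zero
    tpm <- sweep(rate, 2, denom, "/") * 1e6
    m <- log2(tpm + 1)
  } else if (max(m) > log_max_threshold) {
    if (any(m < 0)) {
      iscape_error("value_error",
                   "matrix looks linear-scale but has negative values")
    }
    m <- log2(m + 1)
  }
  study$matrix <- m
  study$log_scale <- TRUE
  study
}

#' Construct a study collection
#'
#' Groups studies into (disease, compartment) strata. Each study must map
#' to exactly one stratum (its samples all share one disease and one
#' compartment).
#'
#' @param studies list of `expression_study` objects.
#' @return object of class `study_collection` with a `strata` data.frame.
#' @export
study_collection <- function(studies) {
  ids <- vapply(studies, function(s) s$study_id, character(1))
  if (anyDuplicated(ids)) {
    iscape_error("consistency_error", "study_ids must be unique")
  }
  strata <- lapply(studies, function(s) {
    d <- unique(s$samples$disease)
    cp <- unique(s$samples$compartment)
    if (length(d) != 1 || length(cp) != 1) {
      iscape_error("consistency_error",
                   "study %s spans multiple (disease, compartment) strata",
                   s$study_id)
    }
    data.frame(study_id = s$study_id, disease = d, compartment = cp,
               n_samples = nrow(s$samples), stringsAsFactors = FALSE)
  })
  names(studies) <- ids
  structure(list(studies = studies,
                 strata = do.call(rbind, strata)),
            class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf("<study_collection> %d studies, %d samples\n",
              length(x$studies), sum(x$strata$n_samples)))
  invisible(x)
}

#' Apply study/sample inclusion filters to a collection
#'
#' Implements the standard inclusion rules for observational case-control
#' meta-analysis: a minimum number of subjects per study, baseline samples
#' only in longitudinal studies, and exclusion of treated samples when
#' treatment information is available. Missing optional metadata passes the
#' corresponding filter (with a logged warning). Studies left without both
#' classes are removed. The operation is idempotent and never increases the
#' number of studies or samples.
#'
#' @param collection a `study_collection`.
#' @param min_patients integer, minimum subjects per study (default 4).
#' @param baseline_only keep only `timepoint == "baseline"` rows where a
#'   timepoint column exists with more than one level.
#' @param untreated_only drop `treated == TRUE` rows where present.
#' @return filtered `study_collection`; per-filter attrition counts in
#'   `attr(, "attrition")`.
#' @export
filter_collection <- function(collection, min_patients = 4,
                              baseline_only = TRUE, untreated_only = TRUE) {
  attrition <- list()
  kept <- list()
  for (s in collection$studies) {
    meta <- s$samples
    keep <- rep(TRUE, nrow(meta))
    if (baseline_only && "timepoint" %in% colnames(meta) &&
        length(unique(stats::na.omit(meta$timepoint))) > 1) {
      keep <- keep & (is.na(meta$timepoint) | meta$timepoint == "baseline")
    }
    if (untreated_only && "treated" %in% colnames(meta)) {
      keep <- keep & !(meta$treated %in% TRUE)
    }
    attrition[[s$study_id]] <- c(samples_dropped = sum(!keep))
    if (sum(keep) < min_patients) {
      attrition[[s$study_id]]["study_dropped_min_patients"] <- 1
      next
    }
    meta_k <- meta[keep, , drop = FALSE]
    if (length(unique(meta_k$class)) < 2) {
      attrition[[s$study_id]]["study_dropped_single_class"] <- 1
      next
    }
    s$matrix <- s$matrix[, keep, drop = FALSE]
    s$samples <- meta_k
    kept[[s$study_id]] <- s
  }
  if (length(kept) == 0) {
    iscape_error("pipeline_error",
                 "no study survives filtering (attrition: %s)",
                 paste(names(attrition), collapse = ", "))
  }
  out <- study_collection(unname(kept))
  attr(out, "attrition") <- attrition
  out
}

#' Load gene sets from a GMT file
#'
#' GMT lines are tab-separated: set name, description, then gene ids.
#' Duplicate genes within a set are deduplicated; empty sets are dropped
#' with a warning.
#'
#' @param gmt_path file path.
#' @param category one of `"pathway"`, `"tf_regulon"`, `"mirna_targets"`,
#'   `"cytokine_panel"`.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of gene-id vectors) and `category`.
#' @export
load_gene_sets <- function(gmt_path,
                           category = c("pathway", "tf_regulon",
                                        "mirna_targets", "cytokine_panel")) {
  category <- match.arg(category)
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      iscape_error("parse_error",
                   "malformed GMT line %d: fewer than 3 tab-separated fields",
                   i)
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      iscape_warn("GMT set '%s' (line %d) is empty; dropped", fields[1], i)
      next
    }
    sets[[fields[1]]] <- genes
  }
  gene_set_collection(sets, category)
}

#' Construct a gene set collection
#'
#' @param sets named list of gene-id character vectors (non-empty, unique
#'   within a set).
#' @param category set category (see [load_gene_sets()]).
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets,
                                category = c("pathway", "tf_regulon",
                                             "mirna_targets",
                                             "cytokine_panel")) {
  category <- match.arg(category)
  if (any(lengths(sets) == 0)) {
    iscape_error("value_error", "gene sets must be non-empty")
  }
  sets <- lapply(sets, unique)
  structure(list(sets = sets, category = category),
            class = "gene_set_collection")
}

#' Write a gene set collection to GMT
#' @param collection a `gene_set_collection`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$category, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a cell-type basis matrix for deconvolution
#'
#' Reference expression (linear scale, non-negative) of marker genes per
#' cell type. A rank-deficient basis on the shared-gene subset makes the
#' mixture model unidentifiable; that is checked and warned about, not
#' enforced.
#'
#' @param matrix non-negative numeric genes x celltypes matrix with gene
#'   rownames and cell-type colnames.
#' @return object of class `basis_matrix`.
#' @export
basis_matrix <- function(matrix) {
  if (any(matrix < 0)) {
    iscape_error("value_error", "basis matrix entries must be non-negative")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    iscape_error("schema_error",
                 "basis matrix needs gene rownames and cell-type colnames")
  }
  if (anyDuplicated(colnames(matrix))) {
    iscape_error("schema_error", "cell-type names must be unique")
  }
  if (qr(matrix)$rank < ncol(matrix)) {
    iscape_warn("basis matrix is column rank deficient; deconvolution may be unidentifiable")
  }
  structure(list(matrix = matrix,
                 gene_ids = rownames(matrix),
                 celltype_names = colnames(matrix)),
            class = "basis_matrix")
}

#' Load a basis matrix from TSV (genes x cell types)
#' @param path file path; first column gene id, header = cell-type names.
#' @return a `basis_matrix`.
#' @export
load_basis_matrix <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(raw[[1]])
  basis_matrix(m)
}
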