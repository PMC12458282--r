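# Higher-order immune features from expression: single-sample gene-set
# enrichment scores, cell-type proportions by non-negative least squares
# against a basis matrix, and cytokine panel expression.

#' Single-sample gene-set enrichment score
#'
#' Genes are ranked by expression (descending; ties broken by input order).
#' Walking down the ranking, two cumulative distributions are accumulated:
#' the in-set distribution weighted by rank^alpha (the gene at position i of
#' N has rank weight (N - i + 1)^alpha) and the unweighted out-of-set
#' distribution. The score is the signed maximum deviation between the two
#' running distributions, which is already normalized: a set occupying the
#' top |S| ranks attains +1 and one occupying the bottom |S| ranks attains
#' -1 regardless of set size. The `"sum"` method instead sums the running
#' difference over all positions and divides by the maximum attainable sum
#' for the set size and alpha (the value reached by the top-ranks
#' configuration). Scores are invariant under strictly monotone transforms
#' of the expression vector.
#'
#' @param expression named numeric vector of gene expression for one
#'   sample.
#' @param gene_set character vector of gene ids.
#' @param alpha rank-weight exponent (default 0.25; 0 gives an unweighted
#'   ECDF).
#' @param method `"max_deviation"` (default) or `"sum"`.
#' @return scalar score in \[-1, 1\].
#' @export
ssgsea_score <- function(expression, gene_set, alpha = 0.25,
                         method = c("max_deviation", "sum")) {
  method <- match.arg(method)
  in_set <- names(expression) %in% gene_set
  n_in <- sum(in_set)
  n <- length(expression)
  if (n_in == 0 || n_in == n) {
    iscape_error("degenerate_error",
                 "gene set must be a non-empty proper subset of the genes")
  }
  ord <- order(expression, decreasing = TRUE)
  .ssgsea_from_order(in_set[ord], alpha, method)
}

# Core statistic given the in-set indicator in ranked order.
.ssgsea_from_order <- function(ind, alpha, method) {
  n <- length(ind)
  w <- (n - seq_len(n) + 1)^alpha
  p_in <- cumsum(w * ind) / sum(w[ind])
  p_out <- cumsum(!ind) / sum(!ind)
  dev <- p_in - p_out
  es <- if (method == "max_deviation") {
    dev[which.max(abs(dev))]
  } else {
    sum(dev) / .ssgsea_max_sum(n, sum(ind), alpha)
  }
  unname(es)
}

# Maximum attainable running-difference sum: the set occupying the top
# ranks.
.ssgsea_max_sum <- function(n, n_in, alpha) {
  ind <- c(rep(TRUE, n_in), rep(FALSE, n - n_in))
  w <- (n - seq_len(n) + 1)^alpha
  sum(cumsum(w * ind) / sum(w[ind]) - cumsum(!ind) / (n - n_in))
}

#' Score every gene set for every sample of a study
#'
#' Sets with fewer than `min_overlap` genes present in the study are
#' dropped with a warning; the drop log is attached as
#' `attr(, "dropped_sets")`.
#'
#' @param study an `expression_study` (log scale).
#' @param sets a `gene_set_collection`.
#' @param alpha,method passed to [ssgsea_score()].
#' @param min_overlap minimum number of set genes present (default 5).
#' @return a `feature_matrix` (sets x samples) with the collection's
#'   category as `feature_type`.
#' @export
featurize_gene_sets <- function(study, sets, alpha = 0.25, min_overlap = 5,
                                method = "max_deviation") {
  genes <- study$gene_ids
  n <- length(genes)
  keep <- vapply(sets$sets, function(s) {
    ov <- sum(genes %in% s)
    ov >= min_overlap && ov < n
  }, logical(1))
  dropped <- names(sets$sets)[!keep]
  if (length(dropped) > 0) {
    iscape_warn("%d gene set(s) below min_overlap = %d dropped: %s",
                length(dropped), min_overlap,
                paste(utils::head(dropped, 5), collapse = ", "))
  }
  use <- sets$sets[keep]
  if (length(use) == 0) {
    iscape_error("pipeline_error",
                 "all gene sets dropped (min_overlap = %d)", min_overlap)
  }
  in_set <- vapply(use, function(s) genes %in% s, logical(n))
  scores <- matrix(NA_real_, length(use), ncol(study$matrix),
                   dimnames = list(names(use), colnames(study$matrix)))
  for (j in seq_len(ncol(study$matrix))) {
    ord <- order(study$matrix[, j], decreasing = TRUE)
    for (i in seq_along(use)) {
      scores[i, j] <- .ssgsea_from_order(in_set[ord, i], alpha, method)
    }
  }
  out <- feature_matrix(scores, feature_type = sets$category,
                        study_id = study$study_id)
  attr(out, "dropped_sets") <- dropped
  attr(out, "params") <- list(alpha = alpha, min_overlap = min_overlap,
                              method = method)
  out
}

#' Construct a feature matrix
#'
#' @param matrix numeric features x samples matrix with dimnames.
#' @param feature_type one of `cell_proportion`, `pathway`, `tf_regulon`,
#'   `mirna_targets`, `cytokine`, or `combined`.
#' @param study_id source study id.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(matrix,
                           feature_type = c("cell_proportion", "pathway",
                                            "tf_regulon", "mirna_targets",
                                            "cytokine", "cytokine_panel",
                                            "combined"),
                           study_id = NA_character_) {
  feature_type <- match.arg(feature_type)
  if (feature_type == "cytokine_panel") feature_type <- "cytokine"
  if (!all(is.finite(matrix))) {
    iscape_error("value_error", "feature matrix must be finite")
  }
  structure(list(feature_ids = rownames(matrix),
                 feature_type = feature_type,
                 matrix = matrix,
                 study_id = study_id),
            class = "feature_matrix")
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes ||A x - b||_2 subject to x >= 0. Small dense problems only
#' (deconvolution bases have a handful of columns).
#'
#' @param A numeric matrix (m x p).
#' @param b numeric vector (length m).
#' @param tol tolerance on the dual feasibility check.
#' @return coefficient vector (length p, >= 0).
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- logical(p)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  max_iter <- 30 * p
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      ratio <- x[neg] / (x[neg] - s[neg])
      amin <- min(ratio[is.finite(ratio)], 1)
      x <- x + amin * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) break
    }
    if (any(passive)) x <- s
    w <- crossprod(A, b - A %*% x)
  }
  pmax(as.vector(x), 0)
}

#' Deconvolve one expression vector into cell-type proportions
#'
#' Solves non-negative least squares of the (linear-scale) expression
#' against the basis on shared genes; mixing is linear in abundance, so
#' log-scale input is de-logged as 2^x - 1 when `delog = TRUE`.
#' Coefficients are clipped at 0 and renormalized to sum to 1.
#'
#' @param expression named numeric vector of gene expression.
#' @param basis a [basis_matrix()].
#' @param delog de-log the expression before fitting (set from the study's
#'   `log_scale` flag by [featurize_cell_proportions()]).
#' @return named proportion vector (non-negative, sums to 1).
#' @export
deconvolve_sample <- function(expression, basis, delog = FALSE) {
  shared <- intersect(names(expression), basis$gene_ids)
  p <- length(basis$celltype_names)
  if (length(shared) < p) {
    iscape_error("insufficient_data_error",
                 "only %d genes shared with the basis (< %d cell types)",
                 length(shared), p)
  }
  y <- expression[shared]
  if (delog) y <- 2^y - 1
  coefs <- nnls_fit(basis$matrix[shared, , drop = FALSE], y)
  if (sum(coefs) == 0) {
    iscape_error("degenerate_error",
                 "all deconvolution coefficients are zero")
  }
  stats::setNames(coefs / sum(coefs), basis$celltype_names)
}

#' Cell-type proportions for every sample of a study
#'
#' @param study an `expression_study`.
#' @param basis a [basis_matrix()].
#' @return a `feature_matrix` of type `cell_proportion` (celltypes x
#'   samples; columns sum to 1).
#' @export
featurize_cell_proportions <- function(study, basis) {
  props <- vapply(seq_len(ncol(study$matrix)), function(j) {
    deconvolve_sample(study$matrix[, j], basis, delog = study$log_scale)
  }, numeric(length(basis$celltype_names)))
  rownames(props) <- basis$celltype_names
  colnames(props) <- colnames(study$matrix)
  feature_matrix(props, feature_type = "cell_proportion",
                 study_id = study$study_id)
}

#' Cytokine panel expression
#'
#' Row-subset of the expression matrix restricted to the panel genes.
#' Missing panel genes are counted and logged.
#'
#' @param study an `expression_study`.
#' @param panel character vector of cytokine gene ids.
#' @return a `feature_matrix` of type `cytokine`; the number of absent
#'   panel genes is in `attr(, "n_missing")`.
#' @export
cytokine_panel <- function(study, panel) {
  panel <- unique(panel)
  present <- intersect(panel, study$gene_ids)
  if (length(present) == 0) {
    iscape_error("degenerate_error",
                 "no cytokine panel gene present in the study")
  }
  n_missing <- length(panel) - length(present)
  if (n_missing > 0) {
    iscape_warn("%d of %d cytokine panel genes absent from study %s",
                n_missing, length(panel), study$study_id)
  }
  out <- feature_matrix(study$matrix[present, , drop = FALSE],
                        feature_type = "cytokine",
                        study_id = study$study_id)
  attr(out, "n_missing") <- n_missing
  out
}

#' Derive all feature families for one study
#'
#' @param study an `expression_study` (log scale).
#' @param sets_by_category list of `gene_set_collection`s (pathways, TF
#'   regulons, miRNA targets); may be empty.
#' @param basis optional [basis_matrix()]; omit to skip cell proportions.
#' @param panel optional cytokine gene-id vector; omit to skip the panel.
#' @param alpha,min_overlap,method passed to [featurize_gene_sets()].
#' @return named list of `feature_matrix` objects, all with the study's
#'   sample ordering.
#' @export
featurize_study <- function(study, sets_by_category = list(), basis = NULL,
                            panel = NULL, alpha = 0.25, min_overlap = 5,
                            method = "max_deviation") {
  out <- list()
  if (!is.null(basis)) {
    out$cell_proportion <- featurize_cell_proportions(study, basis)
  }
  for (sets in sets_by_category) {
    out[[sets$category]] <- featurize_gene_sets(
      study, sets, alpha = alpha, min_overlap = min_overlap, method = method)
  }
  if (!is.null(panel)) {
    out$cytokine <- cytokine_panel(study, panel)
  }
  if (length(out) == 0) {
    iscape_error("value_error", "no feature family requested")
  }
  out
}

#' Stack feature matrices into one combined matrix
#'
#' Feature ids are prefixed with their family (`"pathway:IFN_ALPHA"`) so
#' they stay unique when families are mixed for landscape assembly, module
#' discovery and scoring.
#'
#' @param features a `feature_matrix` or list of them (same samples, same
#'   order).
#' @return a `feature_matrix` of type `combined`; per-row family in
#'   `attr(, "row_type")`.
#' @export
stack_features <- function(features) {
  if (inherits(features, "feature_matrix")) features <- list(features)
  cols <- colnames(features[[1]]$matrix)
  mats <- lapply(features, function(f) {
    if (!identical(colnames(f$matrix), cols)) {
      iscape_error("consistency_error",
                   "feature matrices have mismatched sample columns")
    }
    m <- f$matrix
    rownames(m) <- paste(f$feature_type, rownames(m), sep = ":")
    m
  })
  m <- do.call(rbind, mats)
  row_type <- rep(vapply(features, `[[`, character(1), "feature_type"),
                  vapply(features, function(f) nrow(f$matrix), integer(1)))
  out <- feature_matrix(m, feature_type = "combined",
                        study_id = features[[1]]$study_id)
  attr(out, "row_type") <- row_type
  out
}
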