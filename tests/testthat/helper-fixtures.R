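# Small fixtures built in code; nothing is read from disk except files the
# tests write themselves.

tiny_metadata <- function(n = 4, study_id = "study1", disease = "diseaseA",
                          compartment = "blood", ...) {
  extra <- list(...)
  meta <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    study_id = study_id,
    disease = disease,
    class = rep(c("case", "control"), length.out = n),
    compartment = compartment,
    stringsAsFactors = FALSE)
  for (nm in names(extra)) meta[[nm]] <- extra[[nm]]
  meta
}

tiny_study <- function(n_genes = 3, n = 4, seed = 1, ...) {
  m <- withr::with_seed(seed, matrix(rnorm(n_genes * n, 8, 1), n_genes, n))
  rownames(m) <- sprintf("g%02d", seq_len(n_genes))
  meta <- tiny_metadata(n, ...)
  colnames(m) <- meta$sample_id
  expression_study(meta$study_id[1], m, meta)
}

tiny_basis <- function(n_genes = 90, n_celltypes = 3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_genes * n_celltypes, 1, 10), n_genes, n_celltypes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("ct%d", seq_len(n_celltypes))))
    block <- n_genes %/% n_celltypes
    for (ct in seq_len(n_celltypes)) {
      idx <- ((ct - 1) * block + 1):(ct * block)
      m[idx, ct] <- m[idx, ct] * 8
    }
    basis_matrix(m)
  })
}

# feature matrix of type "combined" with planted per-module class shifts
tiny_feature_world <- function(n_modules = 15, features_per_module = 10,
                               n_case = 20, n_control = 20,
                               shift_module = NULL, shift = 0, seed = 1) {
  nf <- n_modules * features_per_module
  n <- n_case + n_control
  m <- withr::with_seed(seed, matrix(rnorm(nf * n), nf, n))
  rownames(m) <- sprintf("f%03d", seq_len(nf))
  colnames(m) <- sprintf("s%03d", seq_len(n))
  assign <- rep(seq_len(n_modules), each = features_per_module)
  if (!is.null(shift_module)) {
    rows <- assign == shift_module
    m[rows, seq_len(n_case)] <- m[rows, seq_len(n_case)] + shift
  }
  mods <- lapply(seq_len(n_modules),
                 function(i) rownames(m)[assign == i])
  names(mods) <- sprintf("M%02d", seq_len(n_modules))
  list(features = feature_matrix(m, "combined", study_id = "world"),
       modules = module_set(mods),
       labels = rep(c("case", "control"), c(n_case, n_control)),
       assignment = assign)
}

# Independent brute-force ssGSEA oracle: explicit position-by-position
# accumulation of the two rank CDFs.
oracle_ssgsea <- function(expression, gene_set, alpha,
                          method = "max_deviation") {
  ord <- order(expression, decreasing = TRUE)
  genes <- names(expression)[ord]
  n <- length(genes)
  ins <- genes %in% gene_set
  w_tot <- 0
  for (i in seq_len(n)) if (ins[i]) w_tot <- w_tot + (n - i + 1)^alpha
  dev <- numeric(n)
  cin <- 0; cout <- 0
  for (i in seq_len(n)) {
    if (ins[i]) cin <- cin + (n - i + 1)^alpha else cout <- cout + 1
    dev[i] <- cin / w_tot - cout / (n - sum(ins))
  }
  if (method == "max_deviation") dev[which.max(abs(dev))] else sum(dev)
}

# Exhaustive pair-counting AUC oracle.
oracle_auc <- function(case, control) {
  tot <- 0
  for (x in case) for (y in control) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(case) * length(control))
}

# Random landscape with no structure (public generator at correlation 0).
null_landscape <- function(n_features, n_diseases, seed) {
  generate_planted_landscape(synthetic_landscape_config(
    n_features, n_diseases, n_modules = 1,
    within_module_correlation = 0, seed = seed))
}
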