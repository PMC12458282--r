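test_that("ssGSEA hits its extreme values and ignores the expression scale", {
  x <- setNames(c(5, 4, 3, 2, 1, 0), paste0("g", 1:6))
  expect_equal(ssgsea_score(x, c("g1", "g2"), alpha = 0), 1)
  expect_equal(ssgsea_score(x, c("g5", "g6"), alpha = 0), -1)

  # rank invariance under strictly monotone transforms
  withr::with_seed(10, {
    for (i in 1:20) {
      n <- sample(10:40, 1)
      v <- setNames(rnorm(n), paste0("g", seq_len(n)))
      set <- sample(names(v), sample(2:(n - 2), 1))
      s0 <- ssgsea_score(v, set)
      for (f in list(function(z) 2^z, function(z) z^3 + z,
                     function(z) rank(z))) {
        expect_equal(ssgsea_score(f(v), set), s0)
      }
    }
  })
  expect_error(ssgsea_score(x, "absent"), class = "degenerate_error")
  expect_error(ssgsea_score(x, names(x)), class = "degenerate_error")
})

test_that("ssGSEA equals the brute-force running-sum oracle", {
  # exhaustive: every ranking (permutation) and every proper subset, n <= 5
  for (n in 3:5) {
    idx <- seq_len(n)
    perm_list <- asplit(expand.grid(rep(list(idx), n)), 1)
    perm_list <- Filter(function(p) !anyDuplicated(p), perm_list)
    genes <- paste0("g", idx)
    for (p in perm_list) {
      v <- setNames(as.numeric(p), genes)
      for (bits in 1:(2^n - 2)) {
        set <- genes[as.logical(bitwAnd(bits, 2^(idx - 1)))]
        for (alpha in c(0, 0.25)) {
          expect_identical(ssgsea_score(v, set, alpha = alpha),
                           oracle_ssgsea(v, set, alpha))
        }
      }
    }
  }
  # random spot checks at n = 6..8, both methods
  withr::with_seed(11, {
    for (i in 1:100) {
      n <- sample(6:8, 1)
      v <- setNames(sample(n), paste0("g", seq_len(n)))
      set <- sample(names(v), sample(1:(n - 1), 1))
      expect_equal(ssgsea_score(v, set, alpha = 0.25),
                   oracle_ssgsea(v, set, 0.25))
      expect_equal(
        ssgsea_score(v, set, alpha = 0.25, method = "sum"),
        oracle_ssgsea(v, set, 0.25, "sum") /
          immunoscape:::.ssgsea_max_sum(n, length(set), 0.25))
    }
  })
})

test_that("featurize_gene_sets respects shapes, independence and overlap", {
  study <- tiny_study(30, 4, seed = 3)
  sets <- gene_set_collection(list(S1 = rownames(study$matrix)[1:6]),
                              "pathway")
  fm <- featurize_gene_sets(study, sets)
  expect_identical(dim(fm$matrix), c(1L, 4L))
  expect_identical(colnames(fm$matrix), study$samples$sample_id)

  # duplicating a sample column duplicates its score column
  dup <- study
  dup$matrix[, 2] <- dup$matrix[, 1]
  fm2 <- featurize_gene_sets(dup, sets)
  expect_equal(fm2$matrix[, 1], fm2$matrix[, 2], ignore_attr = TRUE)

  small <- gene_set_collection(list(S1 = rownames(study$matrix)[1:6],
                                    TINY = rownames(study$matrix)[1:2]),
                               "pathway")
  expect_warning(fm3 <- featurize_gene_sets(study, small), "min_overlap")
  expect_identical(attr(fm3, "dropped_sets"), "TINY")
  expect_error(
    suppressWarnings(featurize_gene_sets(
      study, gene_set_collection(list(TINY = c("g01", "g02")), "pathway"))),
    class = "pipeline_error")
})

test_that("deconvolution recovers mixtures and flags degenerate inputs", {
  b <- tiny_basis()
  # identity mixture and linear 50/50 mixture, noise-free
  p <- cbind(diag(3), c(.5, .5, 0), c(.2, .3, .5))
  rownames(p) <- b$celltype_names
  colnames(p) <- paste0("s", 1:5)
  ms <- generate_mixture_study(b, p, noise_sd = 0)
  est <- vapply(1:5, function(j) deconvolve_sample(ms$matrix[, j], b),
                numeric(3))
  expect_equal(unname(est), unname(p), tolerance = 1e-8)
  expect_equal(colSums(est), rep(1, 5), ignore_attr = TRUE)

  # 10% noise: per-sample proportion error below 0.05
  ms2 <- generate_mixture_study(b, p, noise_sd = 0.1 * mean(b$matrix),
                                seed = 9)
  est2 <- vapply(1:5, function(j) deconvolve_sample(ms2$matrix[, j], b),
                 numeric(3))
  expect_lt(max(abs(est2 - p)), 0.05)

  expect_error(deconvolve_sample(setNames(1:2, c("g001", "g002")), b),
               class = "insufficient_data_error")

  # featurize_cell_proportions de-logs log-scale studies
  log_ms <- ms
  log_ms$matrix <- log2(ms$matrix + 1)
  log_ms$log_scale <- TRUE
  fp <- featurize_cell_proportions(log_ms, b)
  expect_equal(unname(fp$matrix), unname(p), tolerance = 0.02)
  expect_identical(fp$feature_type, "cell_proportion")
})

test_that("nnls_fit solves interior problems exactly", {
  withr::with_seed(14, {
    for (i in 1:20) {
      A <- matrix(runif(40 * 4, 1, 5), 40, 4)
      x_true <- runif(4, 0.5, 2)
      x_hat <- nnls_fit(A, as.vector(A %*% x_true))
      expect_equal(x_hat, x_true, tolerance = 1e-8)
    }
  })
})

test_that("cytokine panels subset the expression rows", {
  study <- tiny_study(10, 4, seed = 5)
  panel <- rownames(study$matrix)[c(2, 5)]
  cp <- cytokine_panel(study, panel)
  expect_equal(cp$matrix, study$matrix[panel, ])
  expect_identical(cp$feature_type, "cytokine")

  big_panel <- c(panel[1], sprintf("missing%03d", 1:274))
  expect_warning(cp2 <- cytokine_panel(study, big_panel), "274 of 275")
  expect_identical(nrow(cp2$matrix), 1L)
  expect_error(cytokine_panel(study, "nope"), class = "degenerate_error")
})

test_that("featurize_study aligns all families and is deterministic", {
  b <- tiny_basis()
  meta <- tiny_metadata(6)
  m <- withr::with_seed(6, matrix(rnorm(90 * 6, 8, 1), 90, 6,
                                  dimnames = list(rownames(b$matrix),
                                                  meta$sample_id)))
  study <- expression_study("study1", m, meta)
  sets <- list(gene_set_collection(list(P1 = rownames(m)[1:8],
                                        P2 = rownames(m)[11:20]), "pathway"),
               gene_set_collection(list(T1 = rownames(m)[31:40]),
                                   "tf_regulon"),
               gene_set_collection(list(MI1 = rownames(m)[41:50]),
                                   "mirna_targets"))
  fam <- featurize_study(study, sets, basis = b, panel = rownames(m)[1:5])
  expect_named(fam, c("cell_proportion", "pathway", "tf_regulon",
                      "mirna_targets", "cytokine"))
  for (f in fam) expect_identical(colnames(f$matrix), meta$sample_id)
  expect_equal(fam, featurize_study(study, sets, basis = b,
                                    panel = rownames(m)[1:5]))

  no_basis <- featurize_study(study, sets, panel = rownames(m)[1:5])
  expect_false("cell_proportion" %in% names(no_basis))

  stacked <- stack_features(fam)
  expect_identical(stacked$feature_type, "combined")
  expect_true(all(grepl("^(cell_proportion|pathway|tf_regulon|mirna_targets|cytokine):",
                        rownames(stacked$matrix))))
})
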