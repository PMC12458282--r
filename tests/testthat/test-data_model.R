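test_that("expression studies round-trip through TSV with duplicate-gene collapse", {
  dir <- withr::local_tempdir()
  mat_path <- file.path(dir, "mat.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  writeLines(c("gene_id\ts01\ts02\ts03\ts04",
               "TNF\t2\t2\t2\t2",
               "TNF\t4\t4\t4\t4",
               "IL6\t1\t2\t3\t4",
               "CXCL10\t5\t6\t7\t8"),
             mat_path)
  write.table(tiny_metadata(4), meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  study <- load_expression_study(mat_path, meta_path)
  expect_identical(dim(study$matrix), c(3L, 4L))
  expect_equal(unname(study$matrix["TNF", ]), rep(3, 4))

  # write -> load reproduces values to at least 6 decimals
  study$matrix <- study$matrix + pi * 1e-3
  write_expression_study(study, mat_path, meta_path)
  back <- load_expression_study(mat_path, meta_path)
  expect_equal(back$matrix, study$matrix, tolerance = 1e-9)
  expect_identical(back$samples$class, study$samples$class)
})

test_that("loader reports schema and consistency violations", {
  dir <- withr::local_tempdir()
  mat_path <- file.path(dir, "mat.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  writeLines(c("gene_id\ts01\ts02\ts03\ts04",
               "g1\t1\t2\t3\t4"), mat_path)

  meta <- tiny_metadata(4)
  write.table(meta[, setdiff(colnames(meta), "class")], meta_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_expression_study(mat_path, meta_path),
               class = "schema_error")

  meta5 <- tiny_metadata(5)  # s05 not in the matrix header
  write.table(meta5, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_expression_study(mat_path, meta_path),
               class = "consistency_error")
})

test_that("harmonization follows the TPM -> log2 path and is idempotent", {
  meta <- tiny_metadata(2)
  m <- matrix(c(7, 7), 1, 2, dimnames = list("g1", meta$sample_id))
  study <- expression_study("study1", m, meta, platform = "rnaseq",
                            log_scale = FALSE)

  # single gene, count 7, length 1 kb: TPM = 1e6, log2(1e6 + 1)
  h <- harmonize_study(study, counts_are_raw = TRUE,
                       gene_lengths = c(g1 = 1000))
  expect_equal(unname(h$matrix[1, 1]), log2(1e6 + 1))
  expect_true(h$log_scale)

  # all-zero counts stay all-zero
  study0 <- study
  study0$matrix[] <- 0
  h0 <- harmonize_study(study0, counts_are_raw = TRUE,
                        gene_lengths = c(g1 = 1000))
  expect_true(all(h0$matrix == 0))

  # already-log data (max 14.2) pass through unchanged; idempotence
  loggy <- tiny_study(5, 4)
  loggy$matrix[1, 1] <- 14.2
  expect_equal(harmonize_study(loggy)$matrix, loggy$matrix)
  expect_equal(harmonize_study(h)$matrix, h$matrix)

  # linear-scale data above the threshold get log2(x + 1)
  lin <- study
  lin$matrix[] <- c(100, 1000)
  expect_equal(unname(harmonize_study(lin)$matrix[1, ]),
               log2(c(100, 1000) + 1))

  study$matrix[1, 1] <- -1
  expect_error(harmonize_study(study, counts_are_raw = TRUE,
                               gene_lengths = c(g1 = 1000)),
               class = "value_error")
})

test_that("inclusion filters drop small, longitudinal and treated material", {
  small <- tiny_study(3, 3, study_id = "tiny")           # 3 patients
  long <- tiny_study(3, 6, seed = 2, study_id = "long",
                     timepoint = rep(c("baseline", "week12"), 3))
  treated <- tiny_study(3, 6, seed = 3, study_id = "trt",
                        treated = rep(c(FALSE, TRUE), 3))
  ok <- tiny_study(3, 6, seed = 4, study_id = "ok")
  coll <- study_collection(list(small, long, treated, ok))

  f <- filter_collection(coll)
  expect_false("tiny" %in% names(f$studies))
  expect_true(all(f$studies$long$samples$timepoint == "baseline"))
  expect_false(any(f$studies$trt$samples$treated))

  # idempotent and never increasing
  f2 <- filter_collection(f)
  expect_identical(names(f2$studies), names(f$studies))
  expect_identical(f2$strata$n_samples, f$strata$n_samples)

  # a collection already satisfying all filters comes back identical
  ok_coll <- study_collection(list(ok))
  expect_equal(filter_collection(ok_coll)$studies$ok$matrix, ok$matrix)

  expect_error(filter_collection(study_collection(list(small))),
               class = "pipeline_error")
})

test_that("GMT gene sets load with dedup, drops and parse errors", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("SET1\tdesc\tA\tB\tC",
               "SET2\tdesc\tA\tA\tD"), gmt)
  gs <- load_gene_sets(gmt, "pathway")
  expect_length(gs$sets, 2)
  expect_identical(gs$sets$SET2, c("A", "D"))

  writeLines("ONLY_A_NAME", gmt)
  expect_error(load_gene_sets(gmt, "pathway"), class = "parse_error")

  writeLines(c("SET1\tdesc\tA", "EMPTY\tdesc\t\t"), gmt)
  expect_warning(gs2 <- load_gene_sets(gmt, "pathway"), "empty")
  expect_length(gs2$sets, 1)

  # round trip
  write_gene_sets(gs, file.path(dir, "out.gmt"))
  expect_identical(load_gene_sets(file.path(dir, "out.gmt"), "pathway")$sets,
                   gs$sets)
})

test_that("basis matrices enforce non-negativity and warn on rank deficiency", {
  m <- matrix(1:12, 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("ct", 1:3)))
  m[, 3] <- m[, 1] + m[, 2]
  expect_warning(basis_matrix(m), "rank deficient")
  m[1, 1] <- -1
  expect_error(basis_matrix(m), class = "value_error")

  dir <- withr::local_tempdir()
  b <- tiny_basis()
  write.table(data.frame(gene_id = rownames(b$matrix), b$matrix),
              file.path(dir, "basis.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  b2 <- load_basis_matrix(file.path(dir, "basis.tsv"))
  expect_equal(b2$matrix, b$matrix)
})
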