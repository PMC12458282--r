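test_that("module scores are sums of z-scaled features", {
  m <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1,
                5, 5, 5, 5), 3, 4, byrow = TRUE,
              dimnames = list(c("f1", "f2", "f3"), paste0("s", 1:4)))
  fm <- feature_matrix(m, "combined", "study1")
  mods <- module_set(list(A = c("f1", "f3"), B = "f2"))
  # manual z-scaling (constant f3 contributes 0)
  z1 <- (m[1, ] - mean(m[1, ])) / sd(m[1, ])
  z2 <- (m[2, ] - mean(m[2, ])) / sd(m[2, ])
  msm <- module_scores(fm, mods)
  expect_equal(msm$scores["A", ], z1)   # f3 is constant, contributes 0
  expect_equal(msm$scores["B", ], z2)   # singleton = its z-scaled row

  # equivariance: permuting samples permutes score columns identically
  perm <- c(3, 1, 4, 2)
  fm_p <- feature_matrix(m[, perm], "combined", "study1")
  expect_equal(module_scores(fm_p, mods)$scores,
               msm$scores[, perm])

  # module with no present feature scores NA with a warning
  mods2 <- module_set(list(A = "f1", GONE = "nope"))
  expect_warning(msm2 <- module_scores(fm, mods2), "no feature")
  expect_true(all(is.na(msm2$scores["GONE", ])))
  expect_equal(msm2$coverage[["GONE"]], 0)
})

test_that("AUC equals exhaustive pair counting and handles edge cases", {
  labs <- c("case", "case", "control", "control")
  expect_equal(module_auc(c(3, 5, 1, 4), labs)$auc, 0.75)
  expect_equal(module_auc(c(9, 8, 1, 2), labs)$auc, 1)      # separation
  tied <- module_auc(c(2, 2, 2, 2), labs)
  expect_equal(tied$auc, 0.5)
  expect_equal(tied$p, 1)
  expect_error(module_auc(1:3, rep("case", 3)), class = "value_error")

  # brute-force oracle on random inputs with <= 12 samples (with ties)
  withr::with_seed(12, {
    for (i in 1:100) {
      n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
      v <- sample(1:4, n1 + n2, replace = TRUE) + 0.5 * rbinom(n1 + n2, 1, .5)
      labels <- rep(c("case", "control"), c(n1, n2))
      expect_identical(module_auc(v, labels)$auc,
                       oracle_auc(v[seq_len(n1)], v[n1 + seq_len(n2)]))
    }
  })
})

test_that("AUC aggregation is stability-weighted with capped 1/SD", {
  rec <- data.frame(module_id = "M1", study_id = paste0("st", 1:3),
                    disease = "d1", compartment = "blood",
                    auc = c(0.7, 0.7, 0.7), p = c(0.04, 0.2, 0.5),
                    n_case = 10, n_control = 10)
  agg <- aggregate_module_auc(rec)
  expect_equal(agg$mean_auc, 0.7)
  expect_equal(agg$sd_auc, 0)
  expect_equal(agg$stability, 100)   # 1/SD capped at 1/0.01
  expect_equal(agg$combined_p, fisher_combined_p(c(0.04, 0.2, 0.5)))

  one <- aggregate_module_auc(rec[1, ])
  expect_equal(one$mean_auc, 0.7)
  expect_true(is.na(one$stability))  # flagged at k < 2
})

test_that("permutation test is deterministic and detects planted modules", {
  w <- tiny_feature_world(n_modules = 8, features_per_module = 10,
                          shift_module = 1, shift = 1.5, seed = 31)
  r1 <- permutation_module_test("M01", w$modules, w$features, w$labels,
                                n_perm = 200, seed = 5)
  r2 <- permutation_module_test("M01", w$modules, w$features, w$labels,
                                n_perm = 200, seed = 5)
  expect_identical(r1[c("z", "p")], r2[c("z", "p")])
  expect_lt(r1$p, 0.001)
  expect_equal(r1$p_empirical, 1 / 201)

  # a null module is not flagged
  r0 <- permutation_module_test("M02", w$modules, w$features, w$labels,
                                n_perm = 200, seed = 6)
  expect_gt(r0$p, 0.01)

  big <- module_set(list(A = rownames(w$features$matrix)[1:70],
                         B = rownames(w$features$matrix)[71:80]))
  expect_error(permutation_module_test("A", big, w$features, w$labels,
                                       n_perm = 100, seed = 1),
               class = "value_error")
  expect_error(permutation_module_test("M01", w$modules, w$features,
                                       w$labels, n_perm = 10, seed = 1),
               class = "value_error")
})

test_that("response prediction reports direction instead of silently flipping", {
  resp <- rep(c("responder", "non_responder"), each = 2)
  r <- predict_response(c(1, 2, 3, 4), resp)
  expect_equal(r$auc, 0)
  expect_equal(r$directed_auc, 1)
  expect_identical(r$direction, "lower_in_responders")

  r2 <- predict_response(c(9, 8, 1, 2), resp)
  expect_equal(r2$directed_auc, 1)
  expect_identical(r2$direction, "higher_in_responders")
  expect_error(predict_response(1:3, rep("responder", 3)),
               class = "value_error")

  # label-shuffled null: mean AUC near 0.5
  withr::with_seed(13, {
    aucs <- replicate(100, {
      predict_response(rnorm(20), sample(rep(c("responder", "non_responder"),
                                             10)))$auc
    })
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("severity correlation and group comparison behave at the limits", {
  s <- c(1, 3, 2, 5, 4, 6)
  expect_equal(severity_correlation(s, s)$rho, 1)
  expect_equal(severity_correlation(s, -s)$rho, -1)
  expect_error(severity_correlation(s, c(1, 2, NA, NA, NA, NA)),
               class = "insufficient_data_error")
  withr::with_seed(14, {
    rhos <- replicate(100, severity_correlation(rnorm(40), rnorm(40))$rho)
  })
  expect_lt(abs(mean(rhos)), 0.1)

  expect_equal(compare_groups(c(1, 1, 2), c(1, 2, 1))$p, 1)
  expect_equal(compare_groups(c(5, 5, 5), c(5, 5))$p, 1)
  # disjoint ranges at n = 3/3: minimal attainable exact rank-sum p = 0.1
  expect_equal(compare_groups(c(1, 2, 3), c(10, 11, 12))$p, 0.1)
  # invariant under a common monotone transform
  a <- c(0.3, 1.4, 2.2, 0.9)
  b <- c(1.1, 2.5, 0.4)
  expect_equal(compare_groups(a, b)$p, compare_groups(2^a, 2^b)$p)
  expect_error(compare_groups(numeric(0), 1), class = "value_error")
})
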