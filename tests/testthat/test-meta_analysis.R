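test_that("hedges_g matches the printed formulas", {
  # mean diff 1, sd 1, n = 10/10: SMD = 1, g = 1 - 3/71,
  # se = sqrt(20/100 + g^2/40) evaluated at the corrected g
  r <- hedges_g(1, 1, 10, 0, 1, 10)
  g_expect <- 1 * (1 - 3 / (4 * 20 - 9))
  expect_equal(r$g, g_expect)
  expect_equal(r$se, sqrt(20 / 100 + g_expect^2 / 40))

  expect_equal(hedges_g(5, 2, 8, 5, 1, 9)$g, 0)      # equal means

  a <- hedges_g(2, 1, 7, 1, 2, 12)
  b <- hedges_g(1, 2, 12, 2, 1, 7)
  expect_equal(a$g, -b$g)                            # antisymmetry
  expect_equal(a$se, b$se)

  expect_error(hedges_g(1, 0, 5, 0, 0, 5), class = "degenerate_error")
  expect_error(hedges_g(1, 1, 1, 0, 1, 5), class = "value_error")
})

test_that("DerSimonian-Laird tau2 follows the moment formula", {
  same <- data.frame(g = rep(0.4, 4), se = c(.1, .2, .3, .4))
  expect_equal(dersimonian_laird_tau2(same), 0)      # Q = 0

  expect_warning(t1 <- dersimonian_laird_tau2(data.frame(g = 1, se = .2)),
                 "k = 1")
  expect_equal(t1, 0)

  # hand computation: w = 25 each, Q = 8, denom = 75 - 25 = 50
  df <- data.frame(g = c(0.1, 0.5, 0.9), se = 0.2)
  expect_equal(dersimonian_laird_tau2(df), 0.12)

  expect_error(dersimonian_laird_tau2(data.frame(g = c(0, 1), se = c(0, 1))),
               class = "value_error")
})

test_that("random-effects pooling reduces correctly in the limits", {
  one <- list(hedges_g(1, 1, 10, 0, 1, 10))
  pe1 <- suppressWarnings(pool_random_effects(one))
  expect_equal(pe1$estimate, one[[1]]$g)             # k = 1 passthrough
  expect_equal(pe1$se, one[[1]]$se)
  expect_equal(pe1$k, 1L)

  # equal g, equal se: tau2 = 0, estimate = g, se = se/sqrt(k)
  eq <- data.frame(g = rep(0.3, 4), se = rep(0.2, 4))
  pe <- pool_random_effects(eq)
  expect_equal(pe$estimate, 0.3)
  expect_equal(pe$se, 0.2 / 2)
  expect_equal(pe$tau2, 0)

  # hand-derived heterogeneous pool: w* = 1/(0.04 + 0.12) each
  het <- pool_random_effects(data.frame(g = c(0.1, 0.5, 0.9), se = 0.2))
  expect_equal(het$estimate, 0.5)
  expect_equal(het$se, sqrt(1 / (3 / 0.16)))
  expect_equal(het$p, 2 * pnorm(-abs(het$estimate / het$se)))

  expect_error(pool_random_effects(data.frame(g = numeric(0),
                                              se = numeric(0))),
               class = "value_error")
})

test_that("pooling is stationary when adding a study at the pooled mean", {
  # with tau2 held at its estimate, a new study at the current pooled
  # estimate leaves the estimate unchanged and cannot increase the SE
  withr::with_seed(5, {
    for (i in 1:25) {
      k <- sample(2:8, 1)
      df <- data.frame(g = rnorm(k, 0, 0.8), se = runif(k, 0.05, 0.6))
      pe <- pool_random_effects(df)
      df2 <- rbind(df, data.frame(g = pe$estimate, se = runif(1, 0.05, 0.6)))
      pe2 <- pool_random_effects(df2, tau2 = pe$tau2)
      expect_equal(pe2$estimate, pe$estimate)
      expect_lte(pe2$se, pe$se)
    }
  })
})

test_that("BH q-values match the step-up definition and p.adjust", {
  expect_equal(benjamini_hochberg(0.2), 0.2)                 # m = 1
  expect_equal(benjamini_hochberg(c(.01, .02, .03, .04)), rep(.04, 4))
  expect_equal(benjamini_hochberg(rep(0.3, 5)), rep(0.3, 5)) # tie saturation

  withr::with_seed(2, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))^sample(1:3, 1)
      q <- benjamini_hochberg(p)
      expect_equal(q, p.adjust(p, "BH"))
      expect_true(all(q >= p))                     # never below raw p
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-15))       # monotone after sorting
    }
  })
  expect_error(benjamini_hochberg(c(0.5, 1.2)), class = "value_error")
})

test_that("Fisher's method combines p-values against chi-square 2m", {
  expect_equal(fisher_combined_p(0.37), 0.37)               # m = 1
  expect_equal(fisher_combined_p(c(0.5, 0.5)),
               pchisq(-2 * log(0.25), df = 4, lower.tail = FALSE))
  expect_equal(fisher_combined_p(c(1, 1, 1)), 1)
  expect_error(fisher_combined_p(c(0.5, 0)), class = "value_error")
})

test_that("meta_analyze reduces, unions and ignores study order", {
  cfg <- synthetic_study_config(30, 10, 10, true_effects = 0.5, seed = 21)
  s1 <- generate_study(cfg, 1)
  tb1 <- meta_analyze(study_collection(list(s1)))
  # single study: pooled table equals the per-study g table
  case <- s1$matrix[, s1$samples$class == "case"]
  ctrl <- s1$matrix[, s1$samples$class == "control"]
  r5 <- hedges_g(mean(case[5, ]), sd(case[5, ]), ncol(case),
                 mean(ctrl[5, ]), sd(ctrl[5, ]), ncol(ctrl))
  i <- match(rownames(s1$matrix)[5], tb1$entity)
  expect_equal(tb1$estimate[i], r5$g)
  expect_equal(tb1$se[i], r5$se)
  expect_equal(tb1$fdr, benjamini_hochberg(tb1$p))
  expect_true(all(tb1$k == 1))

  # order invariance and union semantics over partially shared genes
  s2 <- generate_study(cfg, 2)
  s2$matrix <- s2$matrix[1:20, ]  # genes 21..30 absent from study 2
  s2$gene_ids <- rownames(s2$matrix)
  ab <- meta_analyze(study_collection(list(s1, s2)))
  ba <- meta_analyze(study_collection(list(s2, s1)))
  expect_equal(ab, ba)
  expect_identical(as.integer(table(ab$k)), c(10L, 20L))
})
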