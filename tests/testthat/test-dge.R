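ordinary <- de_thresholds(moderation = "ordinary")

test_that("paired log fold change and t match the one-sample oracle", {
  st <- paired_study_from_diffs(list(GENE1 = c(1, 2, 3),
                                     GENE2 = c(-1, 0.5, 0.2),
                                     GENE3 = c(4, 4.5, 3.5)))
  res <- fit_differential(st, ordinary)
  g1 <- res[res$gene == "GENE1", ]
  expect_equal(g1$logFC, 2)
  expect_equal(g1$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(g1$p_value, 0.0742, tolerance = 1e-3)
  # textbook one-sample t on the differences, gene by gene
  for (g in res$gene) {
    d <- st$matrix[g, st$design$group == "case"] -
      st$matrix[g, st$design$group == "control"]
    tt <- t.test(d)
    row <- res[res$gene == g, ]
    expect_equal(row$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("unpaired fit matches the pooled-variance two-sample oracle", {
  set.seed(21)
  case <- matrix(rnorm(5 * 4, 7), 5, 4,
                 dimnames = list(paste0("G", 1:5), NULL))
  ctrl <- matrix(rnorm(5 * 3, 7), 5, 3,
                 dimnames = list(paste0("G", 1:5), NULL))
  st <- unpaired_study(case, ctrl)
  res <- fit_differential(st, ordinary)
  for (g in res$gene) {
    tt <- t.test(case[g, ], ctrl[g, ], var.equal = TRUE)
    row <- res[res$gene == g, ]
    expect_equal(row$logFC, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
    expect_equal(row$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("results are invariant to sample column order and label swap", {
  sim <- generate_cohort(60, list(type = "paired", n_pairs = 5),
                         planted = data.frame(gene = "G0003", logfc = 2.5),
                         noise_sd = 0.3, seed = 8)
  st <- sim$study
  res <- fit_differential(st, de_thresholds())

  perm <- sample(ncol(st$matrix))
  st2 <- expression_study(st$matrix[, perm],
                          st$design[match(colnames(st$matrix)[perm],
                                          st$design$sample), ],
                          st$cohort_id)
  expect_equal(fit_differential(st2, de_thresholds()), res)

  des3 <- st$design
  des3$group <- ifelse(des3$group == "case", "control", "case")
  res3 <- fit_differential(expression_study(st$matrix, des3, st$cohort_id),
                           de_thresholds())
  expect_equal(res3$logFC, -res$logFC)
  expect_equal(res3$p_value, res$p_value)
})

test_that("variance moderation recovers the hierarchical-model hyperparameters", {
  # direct formula evaluation
  expect_equal(posterior_variances(3, df = 2, d0 = 4, s0_sq = 1), 5 / 3)
  # constant-variance limit
  mod <- moderate_variances(rep(2.5, 50), df = 6)
  expect_identical(mod$d0, Inf)
  expect_true(all(mod$post_var == mod$post_var[1]))
  expect_equal(mod$post_var[1], 2.5, tolerance = 0.25)
  # convex-combination property and the two degree-of-freedom limits
  set.seed(5)
  s2 <- rchisq(300, df = 4) / 4
  mod <- moderate_variances(s2, df = 4)
  expect_true(all(mod$post_var >= pmin(s2, mod$s0_sq) - 1e-12))
  expect_true(all(mod$post_var <= pmax(s2, mod$s0_sq) + 1e-12))
  expect_equal(posterior_variances(s2, 4, 0, mod$s0_sq), s2)
  expect_equal(posterior_variances(s2, 4, Inf, mod$s0_sq),
               rep(mod$s0_sq, length(s2)))
})

test_that("moderation agrees with the established empirical-Bayes reference", {
  skip_if_not_installed("limma")
  set.seed(17)
  s2 <- rchisq(500, df = 5) / 5 * exp(rnorm(500, sd = 0.8))
  mod <- moderate_variances(s2, df = 5)
  ref <- limma::squeezeVar(s2, df = 5)
  expect_equal(mod$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, ref$var.prior, tolerance = 1e-6)
  expect_equal(mod$post_var, ref$var.post, tolerance = 1e-6)
})

test_that("zero residual variance under ordinary statistics is flagged", {
  st <- paired_study_from_diffs(list(FLAT = c(2, 2, 2),
                                     OK = c(1, 2, 3)))
  expect_warning(res <- fit_differential(st, ordinary), "zero residual")
  expect_identical(res$p_value[res$gene == "FLAT"], 0)
})

test_that("DEG calling applies strict fold-change and inclusive p cutoffs", {
  res <- data.frame(gene = c("A", "B", "C", "D"),
                    logFC = c(2.0, -2.5, 3.0, 1.0),
                    t_stat = 0, p_value = c(0.001, 0.01, 0.05, 0.001),
                    direction = "none", is_deg = FALSE)
  degs <- call_degs(res, de_thresholds())
  expect_false("A" %in% degs$gene)   # |logFC| = 2 exactly fails the strict rule
  expect_true("C" %in% degs$gene)    # p = 0.05 exactly passes the inclusive rule
  expect_identical(degs$direction[degs$gene == "B"], "down")
  expect_identical(degs$gene, c("C", "B"))  # |logFC| descending
})

test_that("planted DE genes are recovered with near-perfect power and rare false calls", {
  recovered <- false_calls <- integer(20)
  planted <- data.frame(gene = sprintf("G%04d", 1:40),
                        logfc = rep(c(3, -3), 20))
  for (i in 1:20) {
    sim <- generate_cohort(1000, list(type = "paired", n_pairs = 14),
                           planted = planted, noise_sd = 0.5, seed = 100 + i)
    degs <- call_degs(fit_differential(sim$study, de_thresholds()),
                      de_thresholds())
    recovered[i] <- length(intersect(degs$gene, planted$gene))
    false_calls[i] <- length(setdiff(degs$gene, planted$gene))
  }
  expect_gte(median(recovered), 38)
  expect_lte(median(false_calls), 1)
})

test_that("volcano table is a lossless reformat", {
  st <- paired_study_from_diffs(list(G1 = c(1, 2, 3), G2 = c(0, 1, -1)))
  res <- fit_differential(st, ordinary)
  v <- volcano_table(res)
  expect_identical(nrow(v), nrow(res))
  expect_equal(v$neg_log10_p, -log10(res$p_value))
  expect_equal(-log10(0.05), 1.3010, tolerance = 1e-4)
  res$p_value[1] <- 1
  expect_identical(volcano_table(res)$neg_log10_p[1], 0)
})

test_that("zero-noise synthetics give exact parameter recovery", {
  planted <- data.frame(gene = c("G0002", "G0007"), logfc = c(3, -2.5))
  sim <- generate_cohort(30, list(type = "unpaired", n_case = 3, n_control = 3),
                         planted = planted, noise_sd = 0, seed = 2)
  expect_warning(res <- fit_differential(sim$study, ordinary), "zero residual")
  expect_identical(res$logFC[match(planted$gene, res$gene)], planted$logfc)
})
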