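test_that("zero-noise cohorts carry the planted effect exactly", {
  sim <- generate_cohort(100, list(type = "unpaired", n_case = 3, n_control = 3),
                         planted = data.frame(gene = "G0001", logfc = 3),
                         noise_sd = 0, seed = 1)
  m <- sim$study$matrix
  des <- sim$study$design
  diff <- rowMeans(m[, des$group == "case"]) -
    rowMeans(m[, des$group == "control"])
  expect_equal(unname(diff["G0001"]), 3, tolerance = 1e-12)
  expect_true(all(diff[setdiff(names(diff), "G0001")] == 0))
})

test_that("paired noise behaves like Normal theory predicts", {
  sim <- generate_cohort(200, list(type = "paired", n_pairs = 14),
                         planted = data.frame(gene = "G0001", logfc = 3),
                         noise_sd = 0.5, seed = 1)
  st <- sim$study
  pair_of <- setNames(st$design$pair_id, st$design$sample)
  case <- st$design$sample[st$design$group == "case"]
  ctrl <- st$design$sample[st$design$group == "control"]
  ctrl <- ctrl[match(pair_of[case], pair_of[ctrl])]
  d <- st$matrix["G0001", case] - st$matrix["G0001", ctrl]
  # mean of 14 pair differences, each Normal(3, 0.5*sqrt(2)): 3-sigma band
  expect_lt(abs(mean(d) - 3), 3 * 0.5 * sqrt(2) / sqrt(14))
  # the shared per-pair offset cancels within pairs but not between samples
  expect_gt(var(st$matrix["G0002", c(case, ctrl)]), var(d))
})

test_that("cohort generation is byte-deterministic and validates input", {
  args <- list(50, list(type = "unpaired", n_case = 3, n_control = 3),
               planted = data.frame(gene = "G0005", logfc = -3),
               noise_sd = 0.4, seed = 11)
  f1 <- tempfile(); f2 <- tempfile(); d1 <- tempfile(); d2 <- tempfile()
  write_expression_study(do.call(generate_cohort, args)$study, f1, d1)
  write_expression_study(do.call(generate_cohort, args)$study, f2, d2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(d1), readLines(d2))

  expect_error(generate_cohort(10, list(type = "unpaired", n_case = 3,
                                        n_control = 3),
                               planted = data.frame(gene = "NOPE", logfc = 2),
                               seed = 1),
               "absent from the universe")
  expect_error(generate_cohort(10, list(type = "paired", n_pairs = 3),
                               genes = c("A", "A", "B"), seed = 1),
               "duplicate")
  expect_error(generate_cohort(10, list(type = "paired", n_pairs = 3),
                               noise_sd = -1, seed = 1), "noise_sd")
})

test_that("annotation generator plants sets verbatim and honors empty categories", {
  uni <- sprintf("G%04d", 1:20)
  planted <- list(KMP = list(KMP_X = uni[1:5]))
  ann <- generate_annotations(uni, sets_per_category = setNames(
    c(0L, 0L, 3L, 3L, 3L, 3L), annotation_categories()),
    planted_enriched = planted, avoid = uni[1:5], seed = 3)
  expect_identical(ann$collections$KMP$sets$KMP_X, sort(uni[1:5]))
  expect_length(ann$collections$PID$sets, 0)
  # empty collection -> valid empty GMT -> zero contribution to any score
  p <- tempfile(fileext = ".gmt")
  write_gmt(ann$collections$PID, p)
  expect_identical(readLines(p), character(0))
  expect_length(read_gmt(p, "PID")$sets, 0)

  g1 <- tempfile(); g2 <- tempfile()
  write_gmt(generate_annotations(uni, planted_enriched = planted,
                                 seed = 5)$collections$KMP, g1)
  write_gmt(generate_annotations(uni, planted_enriched = planted,
                                 seed = 5)$collections$KMP, g2)
  expect_identical(readLines(g1), readLines(g2))

  expect_error(generate_annotations(character(), seed = 1), "non-empty")
  expect_error(generate_annotations(uni, planted_enriched =
    list(KMP = list(S = c("G0001", "ZZZ"))), seed = 1), "outside the universe")
})

test_that("network generator wires exactly the requested neighbors", {
  uni <- c("A", "B", sprintf("N%02d", 1:10))
  net <- generate_network(uni, seeds = c("A", "B"), n_new_neighbors = 2,
                          seed = 4)
  expect_identical(nrow(net$truth), 2L)
  non_seed <- unique(c(net$network$gene_a, net$network$gene_b))
  expect_identical(sort(setdiff(non_seed, c("A", "B"))), net$truth$gene)
  expect_true(all(net$network$gene_a != net$network$gene_b))

  expect_error(generate_network(uni, seeds = c("A", "B"),
                                n_new_neighbors = 11, seed = 1),
               "exceeds available")

  # degenerate all-equal scores still give a deterministic expansion
  tie <- generate_network(uni, seeds = c("A", "B"), n_new_neighbors = 5,
                          score_range = c(900, 900), seed = 4)
  e1 <- expand_seed_set(tie$network, c("A", "B"), k = 3)
  shuffled <- tie$network[rev(seq_len(nrow(tie$network))), ]
  e2 <- expand_seed_set(shuffled, c("A", "B"), k = 3)
  expect_identical(e1$added, e2$added)
  expect_identical(e1$added$gene, sort(tie$truth$gene)[1:3])
})

test_that("drug-table generator plants candidate counts and respects approval", {
  uni <- sprintf("G%04d", 1:10)
  tab <- generate_drug_table(uni, druggable = "G0001", drugs_per_gene = 3,
                             approved_fraction = 1, seed = 2)
  rep1 <- map_drugs("G0001", tab$table)
  expect_identical(rep1$n_drugs, 3L)
  expect_identical(rep1$n_genes, 1L)

  none <- generate_drug_table(uni, druggable = c("G0001", "G0002"),
                              drugs_per_gene = 2, approved_fraction = 0,
                              seed = 2)
  expect_identical(map_drugs(uni, none$table)$n_drugs, 0L)

  # non-druggable genes receive no rows; truth matches the table
  expect_true(all(tab$table$gene == "G0001"))
  expect_identical(tab$truth$n_candidate_drugs, 3L)

  f1 <- tempfile(); f2 <- tempfile()
  write_dgi_table(generate_drug_table(uni, uni[1:3], seed = 9)$table, f1)
  write_dgi_table(generate_drug_table(uni, uni[1:3], seed = 9)$table, f2)
  expect_identical(readLines(f1), readLines(f2))

  shared <- generate_drug_table(uni, uni[1:4], drugs_per_gene = 3,
                                n_distinct_drugs = 5, seed = 7)
  expect_identical(length(unique(shared$table$drug_name)), 5L)
  expect_false(any(duplicated(paste(shared$table$drug_name,
                                    shared$table$gene))))
})
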