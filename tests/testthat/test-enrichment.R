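test_that("hypergeometric tail matches single-term and brute-force enumeration", {
  expect_equal(hypergeom_tail(20, 5, 5, 5), 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(hypergeom_tail(20, 5, 5, 0), 1)
  expect_equal(hypergeom_tail(10, 4, 3, 2), 1 / 3, tolerance = 1e-12)
  expect_error(hypergeom_tail(10, 11, 3, 2), "infeasible")
  expect_error(hypergeom_tail(10, 4, 3, 4), "infeasible")
})

test_that("hypergeometric tail is monotone in k and its pmf sums to one", {
  for (case in list(c(50, 10, 8), c(200, 40, 25), c(1000, 7, 81))) {
    N <- case[1]; K <- case[2]; n <- case[3]
    kmax <- min(K, n)
    tails <- sapply(0:kmax, function(k) hypergeom_tail(N, K, n, k))
    expect_true(all(diff(tails) <= 1e-15))
    pmf <- c(tails[-length(tails)] - tails[-1], tails[length(tails)])
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
})

test_that("BH q-values follow the hand step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_fdr(0.37), 0.37)
  set.seed(9)
  for (m in c(3, 17, 200)) {
    p <- runif(m)
    q <- bh_fdr(p)
    expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))            # BH never decreases a p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("GMT files round-trip and malformed lines are rejected", {
  coll <- gene_set_collection("KEGG", list(S1 = c("B", "A"), S2 = c("C", "D", "A")),
                              c(S1 = "first", S2 = "second"))
  p <- tempfile(fileext = ".gmt")
  write_gmt(coll, p)
  back <- read_gmt(p, "KEGG")
  expect_identical(back$sets, coll$sets)
  expect_identical(collection_universe(back), c("A", "B", "C", "D"))
  writeLines("ONLY_TWO\tfields", p)
  expect_error(read_gmt(p, "KEGG"), "malformed")
  expect_error(gene_set_collection("XX", list(S = "A")), "category")
})

test_that("over-representation analysis flags a fully planted set", {
  uni <- sprintf("U%02d", 1:20)
  coll <- gene_set_collection("KMP", list(PLANTED = uni[1:5]))
  res <- run_ora(uni[1:5], coll, universe = uni)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$q_value, res$p_value)
  expect_true(res$significant)

  # query disjoint from every set: nothing significant, all p = 1
  expect_warning(res0 <- run_ora(c("Z1", "Z2"), coll, universe = uni),
                 "does not intersect")
  expect_identical(sum(res0$significant), 0L)
  expect_true(all(res0$p_value == 1))

  # order invariance
  res_shuf <- run_ora(rev(uni[1:5]), coll, universe = uni)
  expect_identical(res_shuf, res)
})

test_that("the PID list is tested once on the raw p-value", {
  uni <- sprintf("U%02d", 1:40)
  coll <- gene_set_collection("PID", list(A = uni[1:3], B = uni[4:7]))
  res <- run_ora(uni[1:7], coll, universe = uni)
  expect_identical(nrow(res), 1L)   # collapsed to a single list
  expect_identical(res$K_set, 7L)
  expect_equal(res$p_value, 1 / choose(40, 7), tolerance = 1e-12)
  expect_true(res$significant)
})

test_that("gene scores sum category points and match a naive double loop", {
  uni <- sprintf("U%02d", 1:50)
  query <- uni[1:10]
  set.seed(33)
  collections <- lapply(setNames(nm = annotation_categories()), function(cat) {
    gene_set_collection(cat, list(
      S1 = sample(uni, 12), S2 = sample(uni, 8), S3 = sample(uni, 15)))
  })
  ora <- lapply(collections, function(coll) run_ora(query, coll, universe = uni))
  scores <- score_genes(query, ora, collections)
  expect_setequal(scores$gene, query)
  expect_identical(scores$score,
                   as.integer(rowSums(scores[, annotation_categories()])))
  # naive recomputation: loop genes x categories over significant sets
  for (g in scores$gene) {
    pts <- 0L
    for (cat in annotation_categories()) {
      res <- ora[[cat]]
      sig <- res$set_id[res$significant]
      members <- if (cat == "PID" && length(sig)) {
        unlist(collections[[cat]]$sets)
      } else unlist(collections[[cat]]$sets[sig])
      if (g %in% members) pts <- pts + 1L
    }
    expect_identical(scores$score[scores$gene == g], pts)
  }
})

test_that("planted multi-category genes out-rank the rest exactly", {
  uni <- sprintf("U%02d", 1:60)
  query <- uni[1:20]
  hot <- uni[1:10]          # planted into 5 of the 6 categories
  planted <- setNames(lapply(annotation_categories(), function(cat) {
    if (cat == "MF") NULL else setNames(list(hot), paste0(cat, "_P"))
  }), annotation_categories())
  planted <- Filter(Negate(is.null), planted)
  spc <- setNames(c(4L, 0L, 4L, 4L, 4L, 4L), annotation_categories())
  ann <- generate_annotations(uni, sets_per_category = spc,
                              set_size_range = c(4L, 8L),
                              planted_enriched = planted,
                              avoid = query, seed = 14)
  ora <- lapply(ann$collections, function(coll) {
    run_ora(query, coll, universe = uni)
  })
  scores <- score_genes(query, ora, ann$collections)
  expect_true(all(scores$score[scores$gene %in% hot] == 5L))
  expect_true(all(scores$score[!scores$gene %in% hot] <
                    min(scores$score[scores$gene %in% hot])))
  expect_true(all(select_risk_genes(scores) %in% query))
})

test_that("risk-gene selection uses an inclusive cutoff and stable order", {
  scores <- data.frame(gene = c("A", "B", "C", "D"),
                       score = c(2L, 1L, 5L, 2L))
  expect_identical(select_risk_genes(scores), c("C", "A", "D"))
  expect_identical(select_risk_genes(scores, 0), c("C", "A", "D", "B"))
  expect_false("B" %in% select_risk_genes(scores))
})
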