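#' Simulate an expression cohort with planted differential genes
#'
#' Generates a genes x samples log2 expression matrix emulating a normalized
#' microarray cohort. Each gene gets a baseline mean drawn once from
#' Normal(7, 1) (a log2-microarray-like scale); control samples fluctuate
#' around that baseline with Gaussian noise and case samples additionally
#' carry the planted log2 fold change for planted genes. Paired designs share
#' a per-pair random offset drawn from Normal(0, 1), so the within-pair
#' difference cancels it and paired analysis is strictly more powerful than
#' unpaired on the same data.
#'
#' @param n_genes Number of genes in the universe (symbols `G0001`, ...).
#' @param design Either `list(type = "paired", n_pairs = ...)` or
#'   `list(type = "unpaired", n_case = ..., n_control = ...)`.
#' @param planted `data.frame` with columns `gene`, `logfc` (signed, log2
#'   units, non-zero) naming the genes with a planted effect. May be empty.
#' @param noise_sd Per-sample Gaussian noise standard deviation (log2 units).
#' @param seed Integer seed; fully determines the output.
#' @param cohort_id Cohort label.
#' @param genes Optional explicit gene universe (overrides `n_genes`).
#'
#' @return A list with elements `study` (an [expression_study()]) and
#'   `truth` (`data.frame` of planted genes and their log fold changes).
#' @export
#'
#' @examples
#' sim <- generate_cohort(100, list(type = "unpaired", n_case = 3, n_control = 3),
#'                        planted = data.frame(gene = "G0001", logfc = 3),
#'                        noise_sd = 0, seed = 1)
#' sim$truth
generate_cohort <- function(n_genes,
                            design,
                            planted = data.frame(gene = character(),
                                                 logfc = numeric()),
                            noise_sd = 0.5,
                            seed = 1L,
                            cohort_id = "synthetic",
                            genes = NULL) {
  seed <- check_seed(seed)
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(n_genes))
  check_gene_symbols(genes)
  n_genes <- length(genes)
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    check_gene_symbols(planted$gene, "planted")
    missing <- setdiff(planted$gene, genes)
    if (length(missing)) {
      abort("planted genes absent from the universe: %s",
            paste(head(missing, 5L), collapse = ", "))
    }
    if (any(planted$logfc == 0) || anyNA(planted$logfc)) {
      abort("planted log fold changes must be non-zero")
    }
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (n_genes < nrow(planted)) abort("n_genes smaller than the planted list")

  paired <- identical(design$type, "paired")
  if (paired) {
    n_pairs <- design$n_pairs
    if (is.null(n_pairs) || n_pairs < 2L) abort("paired design needs n_pairs >= 2")
    n_case <- n_ctrl <- n_pairs
  } else if (identical(design$type, "unpaired")) {
    n_case <- design$n_case; n_ctrl <- design$n_control
    if (is.null(n_case) || is.null(n_ctrl) || n_case < 2L || n_ctrl < 2L) {
      abort("unpaired design needs n_case >= 2 and n_control >= 2")
    }
  } else {
    abort("design$type must be 'paired' or 'unpaired'")
  }

  effect <- setNames(numeric(n_genes), genes)
  if (nrow(planted)) effect[planted$gene] <- planted$logfc

  withr::with_seed(seed, {
    mu <- rnorm(n_genes, mean = 7, sd = 1)
    n_samp <- n_case + n_ctrl
    noise <- matrix(rnorm(n_genes * n_samp, sd = noise_sd), n_genes, n_samp)
    m <- mu + noise
    if (paired) {
      pair_offset <- rnorm(n_case, mean = 0, sd = 1)
      # columns 1..n_pairs are cases, n_pairs+1..2n are their controls
      m[, seq_len(n_case)] <- m[, seq_len(n_case)] +
        rep(pair_offset, each = n_genes)
      m[, n_case + seq_len(n_ctrl)] <- m[, n_case + seq_len(n_ctrl)] +
        rep(pair_offset, each = n_genes)
    }
    m[, seq_len(n_case)] <- m[, seq_len(n_case)] + effect
  })

  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_ctrl)))
  dimnames(m) <- list(genes, samples)
  des <- data.frame(
    sample = samples,
    group = rep(c("case", "control"), c(n_case, n_ctrl)),
    pair_id = if (paired) rep(sprintf("P%02d", seq_len(n_case)), 2) else NA,
    stringsAsFactors = FALSE
  )
  truth <- planted[order(planted$gene), , drop = FALSE]
  rownames(truth) <- NULL
  list(study = expression_study(m, des, cohort_id), truth = truth)
}

#' Simulate GMT annotation collections with planted enriched sets
#'
#' Builds one gene-set collection per requested category. Decoy sets are
#' drawn at random from the universe (preferentially avoiding a designated
#' `query` list so they stay unenriched); planted sets are taken verbatim
#' from `planted_enriched`, giving full control over downstream
#' over-representation significance.
#'
#' @param universe Character vector of gene symbols.
#' @param categories Category names; defaults to all six
#'   ([annotation_categories()]).
#' @param sets_per_category Number of decoy sets per category (0 allowed);
#'   either a single count or a named vector giving one count per category.
#' @param set_size_range Length-2 integer range of decoy set sizes (>= 2).
#' @param planted_enriched Named list `category -> list(set_id = members)`;
#'   members must lie inside `universe`.
#' @param avoid Optional gene list decoy sets should avoid (typically the
#'   intended query), so that only planted sets come out enriched.
#' @param seed Integer seed.
#'
#' @return A list with `collections` (named list of
#'   [gene_set_collection()] objects) and `truth` (`data.frame`
#'   category/set_id/size of the planted sets).
#' @export
generate_annotations <- function(universe,
                                 categories = annotation_categories(),
                                 sets_per_category = 20L,
                                 set_size_range = c(5L, 30L),
                                 planted_enriched = list(),
                                 avoid = character(),
                                 seed = 1L) {
  seed <- check_seed(seed)
  if (!length(universe)) abort("`universe` must be non-empty")
  check_gene_symbols(universe)
  bad_cat <- setdiff(names(planted_enriched), categories)
  if (length(bad_cat)) abort("planted categories not requested: %s",
                             paste(bad_cat, collapse = ", "))
  for (cat in names(planted_enriched)) {
    for (sid in names(planted_enriched[[cat]])) {
      members <- planted_enriched[[cat]][[sid]]
      if (length(members) < 2L) abort("planted set %s has fewer than 2 genes", sid)
      outside <- setdiff(members, universe)
      if (length(outside)) {
        abort("planted set %s contains genes outside the universe: %s",
              sid, paste(head(outside, 5L), collapse = ", "))
      }
    }
  }
  pool <- setdiff(universe, avoid)
  if (length(pool) < max(set_size_range)) pool <- universe

  collections <- setNames(vector("list", length(categories)), categories)
  truth <- list()
  withr::with_seed(seed, {
    for (cat in categories) {
      sets <- list()
      planted <- planted_enriched[[cat]]
      for (sid in names(planted)) {
        sets[[sid]] <- sort(planted[[sid]])
        truth[[length(truth) + 1L]] <-
          data.frame(category = cat, set_id = sid,
                     size = length(planted[[sid]]))
      }
      n_decoy <- if (length(sets_per_category) > 1L) {
        if (is.null(names(sets_per_category)) ||
            !cat %in% names(sets_per_category)) {
          abort("per-category sets_per_category must be named for every category")
        }
        sets_per_category[[cat]]
      } else sets_per_category
      if (n_decoy > 0L) {
        for (i in seq_len(n_decoy)) {
          sz <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
          sets[[sprintf("%s_SET%03d", cat, i)]] <-
            sort(sample(pool, min(sz, length(pool))))
        }
      }
      collections[[cat]] <- gene_set_collection(cat, sets)
    }
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(category = character(), set_id = character(), size = integer())
  list(collections = collections, truth = truth)
}

#' Simulate a scored gene-gene interaction network
#'
#' Emulates a STRING-style edge snapshot around a seed gene set: exactly
#' `n_new_neighbors` distinct non-seed genes each receive one or more scored
#' edges to seed genes, and a handful of seed-seed edges are added so that
#' downstream expansion must deduplicate. Scores are integers in
#' `score_range` (STRING combined-score scale, 0-1000). No self-loops and at
#' most one edge per unordered pair are emitted.
#'
#' @param universe Gene symbols available.
#' @param seeds Seed genes (subset of `universe`).
#' @param n_new_neighbors How many distinct non-seed neighbor genes to wire
#'   to the seed set.
#' @param score_range Length-2 integer range inside \[0, 1000\].
#' @param seed Integer seed.
#' @param extra_edges_per_neighbor Upper bound on additional seed anchors per
#'   neighbor (default 2; drawn uniformly).
#'
#' @return A list with `network` (`data.frame` `gene_a`, `gene_b`,
#'   `combined_score`) and `truth` (`data.frame` of neighbor genes with their
#'   best planted score).
#' @export
generate_network <- function(universe, seeds, n_new_neighbors,
                             score_range = c(400L, 999L), seed = 1L,
                             extra_edges_per_neighbor = 2L) {
  seed <- check_seed(seed)
  check_gene_symbols(universe)
  if (!length(seeds)) abort("`seeds` must be non-empty")
  if (!all(seeds %in% universe)) abort("seeds must be a subset of the universe")
  candidates <- setdiff(universe, seeds)
  if (n_new_neighbors > length(candidates)) {
    abort("n_new_neighbors (%d) exceeds available non-seed genes (%d)",
          n_new_neighbors, length(candidates))
  }
  if (score_range[1] < 0 || score_range[2] > 1000 ||
      score_range[1] > score_range[2]) {
    abort("score_range must lie within [0, 1000]")
  }
  seeds <- sort(unique(seeds))
  edges <- list()
  withr::with_seed(seed, {
    neighbors <- sort(sample(candidates, n_new_neighbors))
    draw_score <- function(n) {
      if (score_range[1] == score_range[2]) rep(score_range[1], n)
      else sample(seq(score_range[1], score_range[2]), n, replace = TRUE)
    }
    for (g in neighbors) {
      n_anchor <- 1L + sample(0:extra_edges_per_neighbor, 1L)
      anchors <- sample(seeds, min(n_anchor, length(seeds)))
      edges[[length(edges) + 1L]] <- data.frame(
        gene_a = anchors, gene_b = g,
        combined_score = draw_score(length(anchors)))
    }
    # seed-seed edges exercise deduplication against the candidate ranking
    if (length(seeds) >= 2L) {
      n_ss <- min(length(seeds), 10L)
      a <- sample(seeds, n_ss)
      b <- sample(seeds, n_ss)
      keep <- a != b
      if (any(keep)) {
        edges[[length(edges) + 1L]] <- data.frame(
          gene_a = a[keep], gene_b = b[keep],
          combined_score = draw_score(sum(keep)))
      }
    }
  })
  net <- do.call(rbind, edges)
  # collapse duplicate unordered pairs, keeping the maximum score
  key <- ifelse(net$gene_a < net$gene_b,
                paste(net$gene_a, net$gene_b),
                paste(net$gene_b, net$gene_a))
  ord <- order(key, -net$combined_score)
  net <- net[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  rownames(net) <- NULL
  is_seed_a <- net$gene_a %in% seeds
  is_seed_b <- net$gene_b %in% seeds
  nb <- ifelse(is_seed_a & !is_seed_b, net$gene_b,
               ifelse(is_seed_b & !is_seed_a, net$gene_a, NA))
  best <- tapply(net$combined_score[!is.na(nb)], nb[!is.na(nb)], max)
  truth <- data.frame(gene = names(best), best_score = as.integer(best),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene), ]
  rownames(truth) <- NULL
  list(network = net, truth = truth)
}

#' Simulate a drug-gene interaction snapshot
#'
#' Emulates a DGIdb-style export: each druggable gene receives
#' `drugs_per_gene` rows of (drug, gene, interaction type, approval). Genes
#' outside `druggable` receive no rows. A fraction of rows can be marked
#' unapproved, and a fraction can carry an empty interaction type, to
#' exercise the downstream "FDA-approved with clear interaction type"
#' filter.
#'
#' @param universe Gene symbols available.
#' @param druggable Genes to receive drug rows (subset of `universe`).
#' @param drugs_per_gene Rows per druggable gene.
#' @param approved_fraction Proportion of rows flagged approved (0-1).
#' @param interaction_types Vocabulary to draw non-empty types from.
#' @param seed Integer seed.
#' @param n_distinct_drugs Optional cap on the number of distinct drug names;
#'   when smaller than `drugs_per_gene * |druggable|` the pool is reused so
#'   some drugs target several genes. Default: every row gets its own drug.
#' @param untyped_fraction Proportion of rows with a blank interaction type.
#' @param drug_prefix Prefix for generated drug names.
#'
#' @return A list with `table` (`data.frame` `drug_name`, `gene`,
#'   `interaction_type`, `approved`) and `truth` (`data.frame` of genes with
#'   their count of approved, typed drugs).
#' @export
generate_drug_table <- function(universe, druggable, drugs_per_gene = 3L,
                                approved_fraction = 1,
                                interaction_types = c("inhibitor", "agonist",
                                                      "antagonist", "modulator"),
                                seed = 1L,
                                n_distinct_drugs = NULL,
                                untyped_fraction = 0,
                                drug_prefix = "DRUG") {
  seed <- check_seed(seed)
  check_gene_symbols(universe)
  if (!all(druggable %in% universe)) {
    abort("druggable genes must be a subset of the universe")
  }
  if (approved_fraction < 0 || approved_fraction > 1) {
    abort("approved_fraction must lie in [0, 1]")
  }
  druggable <- sort(unique(druggable))
  n_rows <- length(druggable) * drugs_per_gene
  if (is.null(n_distinct_drugs)) n_distinct_drugs <- n_rows
  if (n_rows > 0 && (n_distinct_drugs < 1L || n_distinct_drugs > n_rows)) {
    abort("n_distinct_drugs must lie in [1, %d]", n_rows)
  }
  if (n_rows == 0L) {
    tab <- data.frame(drug_name = character(), gene = character(),
                      interaction_type = character(), approved = character())
    return(list(table = tab,
                truth = data.frame(gene = character(), n_candidate_drugs = integer())))
  }
  pool <- sprintf("%s%03d", drug_prefix, seq_len(n_distinct_drugs))
  withr::with_seed(seed, {
    # first |pool| rows take each drug once, the rest reuse the pool
    drugs <- c(pool, if (n_rows > n_distinct_drugs)
      sample(pool, n_rows - n_distinct_drugs, replace = TRUE))
    genes <- rep(druggable, each = drugs_per_gene)
    # a drug must not hit the same gene twice; re-draw collisions
    for (i in seq_along(drugs)) {
      same_gene <- drugs[seq_len(i - 1L)][genes[seq_len(i - 1L)] == genes[i]]
      while (i > n_distinct_drugs && drugs[i] %in% same_gene) {
        drugs[i] <- sample(pool, 1L)
      }
    }
    types <- sample(interaction_types, n_rows, replace = TRUE)
    n_untyped <- round(untyped_fraction * n_rows)
    if (n_untyped > 0) types[sample(n_rows, n_untyped)] <- ""
    n_approved <- round(approved_fraction * n_rows)
    approved <- rep("no", n_rows)
    if (n_approved > 0) approved[sample(n_rows, n_approved)] <- "yes"
  })
  tab <- data.frame(drug_name = drugs, gene = genes,
                    interaction_type = types, approved = approved,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene, tab$drug_name), ]
  rownames(tab) <- NULL
  ok <- tab$approved == "yes" & nzchar(trimws(tab$interaction_type))
  cnt <- tapply(ok, tab$gene, sum)
  truth <- data.frame(gene = names(cnt), n_candidate_drugs = as.integer(cnt),
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(table = tab, truth = truth)
}

#' Write an interaction network TSV
#' @param network `data.frame` with `gene_a`, `gene_b`, `combined_score`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interaction_network <- function(network, path) {
  write_tsv(network[, c("gene_a", "gene_b", "combined_score")], path)
}

#' Write a drug-gene interaction TSV
#' @param table `data.frame` with `drug_name`, `gene`, `interaction_type`,
#'   `approved`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dgi_table <- function(table, path) {
  write_tsv(table[, c("drug_name", "gene", "interaction_type", "approved")],
            path)
}
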