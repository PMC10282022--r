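# Orchestration: synthetic bundle emission, config handling, and the
# end-to-end five-stage run with a machine-readable report.

# Distribute each gene's point count over the six categories so that the
# per-category totals hit `capacities` exactly: classic bipartite
# degree-sequence construction (largest remaining capacity first, ties by
# category name). Errors if the margins are infeasible.
assign_memberships <- function(genes, degrees, capacities) {
  stopifnot(length(genes) == length(degrees),
            sum(degrees) == sum(capacities))
  M <- matrix(0L, length(genes), length(capacities),
              dimnames = list(genes, names(capacities)))
  remaining <- capacities
  for (i in order(-degrees)) {
    d <- degrees[i]
    if (d == 0L) next
    pick <- names(remaining)[order(-remaining, names(remaining))][seq_len(d)]
    if (any(remaining[pick] <= 0L)) {
      abort("infeasible score design: category capacities exhausted")
    }
    M[i, pick] <- 1L
    remaining[pick] <- remaining[pick] - 1L
  }
  stopifnot(all(remaining == 0L))
  M
}

#' Emit the full synthetic input bundle with planted ground truth
#'
#' Generates, in one call, everything the pipeline consumes: two expression
#' cohorts (one paired, one unpaired) sharing a planted overlap of
#' differential genes, a scored interaction network guaranteeing enough
#' non-seed neighbors for the expansion stage, six annotation collections
#' whose planted enriched sets encode a designed score distribution, and a
#' drug-gene snapshot planting a druggable subset of the risk genes. The
#' defaults mirror the reference study's structure: 14 case/control pairs in
#' the paired cohort, 6 vs 3 in the unpaired cohort, planted effects of
#' magnitude 3 log2 units with noise SD 0.5, a 31-gene shared overlap that
#' expands to 81 genes at k = 50, 50 genes designed to reach annotation
#' score >= 2 (with per-category point totals KMP 31, PID 7, KEGG 28, BP 47,
#' CC 22, MF 38 and five genes scoring 5), of which 12 carry 31 distinct
#' approved, typed drugs.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; fully determines every emitted byte.
#' @param n_genes Universe size.
#' @param n_pairs Pairs in the paired cohort.
#' @param n_case,n_control Group sizes in the unpaired cohort.
#' @param planted_lfc Magnitude of planted log2 fold changes.
#' @param noise_sd Per-sample noise SD (log2 units).
#' @param n_shared Planted genes shared by both cohorts (the intended
#'   overlap).
#' @param n_extra_a,n_extra_b Cohort-specific planted genes.
#' @param n_neighbors Distinct scored non-seed neighbors wired to the
#'   overlap seeds.
#' @param k Expansion size the annotation design targets (default 50).
#' @param decoy_sets Decoy gene sets per non-PID category.
#'
#' @return Invisibly, a list with `paths` (named file paths) and `truth`
#'   (the planted ground truth, also written to `truth.json`).
#' @export
simulate_bundle <- function(outdir, seed = 42L, n_genes = 1000L,
                            n_pairs = 14L, n_case = 6L, n_control = 3L,
                            planted_lfc = 3, noise_sd = 0.5,
                            n_shared = 31L, n_extra_a = 9L, n_extra_b = 14L,
                            n_neighbors = 60L, k = 50L, decoy_sets = 20L) {
  seed <- check_seed(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genes <- sprintf("G%04d", seq_len(n_genes))
  shared <- genes[100 + seq_len(n_shared)]
  extra_a <- genes[200 + seq_len(n_extra_a)]
  extra_b <- genes[300 + seq_len(n_extra_b)]

  # predominance of downregulation, as in ulcer-versus-normal skin cohorts
  signed <- function(gs, n_up) {
    data.frame(gene = gs,
               logfc = rep(c(planted_lfc, -planted_lfc),
                           c(n_up, length(gs) - n_up)))
  }
  planted_a <- rbind(signed(shared, 6L), signed(extra_a, 1L))
  planted_b <- rbind(signed(shared, 6L), signed(extra_b, 3L))

  sim_a <- generate_cohort(n_genes, list(type = "paired", n_pairs = n_pairs),
                           planted_a, noise_sd, seed = seed + 1L,
                           cohort_id = "cohortA", genes = genes)
  sim_b <- generate_cohort(n_genes,
                           list(type = "unpaired", n_case = n_case,
                                n_control = n_control),
                           planted_b, noise_sd, seed = seed + 2L,
                           cohort_id = "cohortB", genes = genes)

  net <- generate_network(genes, seeds = shared, n_new_neighbors = n_neighbors,
                          seed = seed + 3L)
  expanded <- expand_seed_set(net$network, shared, k = k)
  query <- expanded$genes
  added <- expanded$added$gene

  # score design over the expanded set: the k network-added genes carry the
  # high scores (5,4,3,2) and the seeds carry single annotations, so exactly
  # 50 genes reach the risk cutoff with per-category totals matching the
  # reference stage counts
  capacities <- c(KMP = 31L, PID = 7L, KEGG = 28L, BP = 47L, CC = 22L,
                  MF = 38L)
  stopifnot(length(added) == 50L, length(shared) == 31L)
  degrees <- c(rep(c(5L, 4L, 3L, 2L), c(5L, 10L, 7L, 28L)),
               rep(1L, length(shared)))
  design_genes <- c(added, sort(shared))
  M <- assign_memberships(design_genes, degrees, capacities)

  planted_sets <- lapply(ANNOTATION_CATEGORIES, function(cat) {
    members <- design_genes[M[, cat] == 1L]
    setNames(list(sort(members)), paste0(cat, "_PLANTED"))
  })
  names(planted_sets) <- ANNOTATION_CATEGORIES
  spc <- setNames(rep(decoy_sets, 6L), ANNOTATION_CATEGORIES)
  spc["PID"] <- 0L  # the PID annotation is one curated list, no decoys
  ann <- generate_annotations(genes, sets_per_category = spc,
                              planted_enriched = planted_sets,
                              avoid = query, seed = seed + 4L)

  scores <- setNames(as.integer(rowSums(M)), design_genes)
  risk <- names(scores)[scores >= 2L]
  druggable <- added[1:12]
  drugs <- generate_drug_table(genes, druggable, drugs_per_gene = 3L,
                               approved_fraction = 1, seed = seed + 5L,
                               n_distinct_drugs = 31L)
  decoy_pool <- setdiff(genes, c(query, extra_a, extra_b))
  decoy_genes <- head(decoy_pool, 5L)
  decoy_drugs <- generate_drug_table(genes, decoy_genes, drugs_per_gene = 2L,
                                     approved_fraction = 0.5,
                                     seed = seed + 6L,
                                     untyped_fraction = 0.3,
                                     drug_prefix = "XDRUG")
  dgi <- rbind(drugs$table, decoy_drugs$table)
  dgi <- dgi[order(dgi$gene, dgi$drug_name), ]

  paths <- c(
    cohortA_expression = file.path(outdir, "cohortA_expression.tsv"),
    cohortA_design = file.path(outdir, "cohortA_design.tsv"),
    cohortB_expression = file.path(outdir, "cohortB_expression.tsv"),
    cohortB_design = file.path(outdir, "cohortB_design.tsv"),
    setNames(file.path(outdir, sprintf("annotation_%s.gmt",
                                       ANNOTATION_CATEGORIES)),
             paste0("gmt_", ANNOTATION_CATEGORIES)),
    network = file.path(outdir, "network.tsv"),
    dgi = file.path(outdir, "dgi.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_expression_study(sim_a$study, paths["cohortA_expression"],
                         paths["cohortA_design"])
  write_expression_study(sim_b$study, paths["cohortB_expression"],
                         paths["cohortB_design"])
  for (cat in ANNOTATION_CATEGORIES) {
    write_gmt(ann$collections[[cat]], paths[paste0("gmt_", cat)])
  }
  write_interaction_network(net$network, paths["network"])
  write_dgi_table(dgi, paths["dgi"])

  truth <- list(
    seed = seed,
    conditions = list(n_genes = n_genes, n_pairs = n_pairs, n_case = n_case,
                      n_control = n_control, planted_lfc = planted_lfc,
                      noise_sd = noise_sd, k = k),
    cohortA = list(planted = sim_a$truth,
                   n_planted = nrow(sim_a$truth),
                   n_up = sum(sim_a$truth$logfc > 0),
                   n_down = sum(sim_a$truth$logfc < 0)),
    cohortB = list(planted = sim_b$truth,
                   n_planted = nrow(sim_b$truth),
                   n_up = sum(sim_b$truth$logfc > 0),
                   n_down = sum(sim_b$truth$logfc < 0)),
    overlap = sort(shared),
    n_overlap = length(shared),
    expansion = list(added = added, n_expanded = length(query)),
    enrichment = list(
      planted_set_ids = setNames(lapply(planted_sets, names),
                                 ANNOTATION_CATEGORIES),
      category_points = as.list(setNames(as.integer(colSums(M)), colnames(M))),
      gene_scores = as.list(scores),
      top_genes = design_genes[degrees == 5L]
    ),
    risk_genes = sort(risk),
    n_risk = length(risk),
    drugs = list(druggable = sort(druggable),
                 n_druggable = length(druggable),
                 n_drugs = length(unique(drugs$table$drug_name)))
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows")
  log_line("simulate", "bundle written to %s (seed %d)", outdir, seed)
  invisible(list(paths = paths, truth = truth))
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. All
#' thresholds default to the reference procedure: `|logFC| > 2`,
#' `p <= 0.05`, empirical-Bayes moderation, expansion `k = 50`, risk-gene
#' score cutoff 2.
#'
#' @param input_dir Directory holding a [simulate_bundle()]-style bundle, or
#'   `NULL` if all paths are given explicitly in `...`.
#' @param outdir Output directory for stage artifacts and the run report.
#' @param ... Overrides for any config field: `cohort_a` / `cohort_b`
#'   (lists with `expression`, `design`, `id`), `gmt` (named list of six
#'   GMT paths), `network`, `dgi`, `lfc`, `alpha`, `moderation`, `k`,
#'   `score_cutoff`, `pid_universe` (`"measured"` or `"annotated"`),
#'   `seed`.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(input_dir = NULL, outdir = "pipeline_out", ...) {
  cfg <- list(
    cohort_a = NULL, cohort_b = NULL, gmt = NULL,
    network = NULL, dgi = NULL,
    lfc = 2, alpha = 0.05, moderation = "eBayes",
    k = 50L, score_cutoff = 2L, pid_universe = "measured",
    outdir = outdir, seed = 42L
  )
  if (!is.null(input_dir)) {
    cfg$cohort_a <- list(expression = file.path(input_dir, "cohortA_expression.tsv"),
                         design = file.path(input_dir, "cohortA_design.tsv"),
                         id = "cohortA")
    cfg$cohort_b <- list(expression = file.path(input_dir, "cohortB_expression.tsv"),
                         design = file.path(input_dir, "cohortB_design.tsv"),
                         id = "cohortB")
    cfg$gmt <- setNames(as.list(file.path(input_dir,
                                          sprintf("annotation_%s.gmt",
                                                  ANNOTATION_CATEGORIES))),
                        ANNOTATION_CATEGORIES)
    cfg$network <- file.path(input_dir, "network.tsv")
    cfg$dgi <- file.path(input_dir, "dgi.tsv")
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_pipeline_config(cfg)
}

config_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("dfurepo_config_error", "error")))
}

stage_error <- function(stage, fmt, ...) {
  stop(errorCondition(sprintf("stage '%s': %s", stage, sprintf(fmt, ...)),
                      class = c("dfurepo_stage_error", "error")))
}

validate_pipeline_config <- function(cfg) {
  for (side in c("cohort_a", "cohort_b")) {
    co <- cfg[[side]]
    if (is.null(co$expression) || is.null(co$design)) {
      config_error("%s needs `expression` and `design` paths", side)
    }
    for (p in c(co$expression, co$design)) {
      if (!file.exists(p)) config_error("missing input file: %s", p)
    }
  }
  if (!setequal(names(cfg$gmt), ANNOTATION_CATEGORIES)) {
    config_error("`gmt` must name exactly the six categories: %s",
                 paste(ANNOTATION_CATEGORIES, collapse = ", "))
  }
  for (p in c(unlist(cfg$gmt), cfg$network, cfg$dgi)) {
    if (!file.exists(p)) config_error("missing input file: %s", p)
  }
  if (cfg$lfc < 0) config_error("lfc must be >= 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) config_error("alpha must lie in (0, 1)")
  if (!cfg$moderation %in% c("eBayes", "ordinary")) {
    config_error("moderation must be 'eBayes' or 'ordinary'")
  }
  if (cfg$k < 0) config_error("k must be >= 0")
  if (cfg$score_cutoff < 0) config_error("score_cutoff must be >= 0")
  if (!cfg$pid_universe %in% c("measured", "annotated")) {
    config_error("pid_universe must be 'measured' or 'annotated'")
  }
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @return A validated `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  base <- pipeline_defaults_for_merge()
  base[names(cfg)] <- cfg
  validate_pipeline_config(base)
}

pipeline_defaults_for_merge <- function() {
  list(cohort_a = NULL, cohort_b = NULL, gmt = NULL, network = NULL,
       dgi = NULL, lfc = 2, alpha = 0.05, moderation = "eBayes", k = 50L,
       score_cutoff = 2L, pid_universe = "measured",
       outdir = "pipeline_out", seed = 42L)
}

#' Run the full drug-repositioning pipeline
#'
#' Executes the five stages — differential expression per cohort,
#' cross-cohort intersection, network expansion, six-category annotation
#' scoring, and drug mapping — writing every stage's TSV artifact plus a
#' consistency-checked JSON run report to `config$outdir`. A structured log
#' line per stage goes to stderr and to `run.log` in the output directory.
#'
#' @param config A [pipeline_config()] (or a path readable by
#'   [read_pipeline_config()]).
#' @return Invisibly, the run report (a list; also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "PipelineConfig")) {
    config <- validate_pipeline_config(config)
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(outdir, "run.log")
  log_con <- file(log_file, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_both <- function(stage, fmt, ...) {
    txt <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    writeLines(txt, log_con)
    message(txt)
  }
  run <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        if (inherits(e, "dfurepo_stage_error")) stop(e)
        stage_error(stage, "%s", conditionMessage(e))
      }),
      message = function(m) writeLines(trimws(conditionMessage(m)), log_con)
    )
  }
  thr <- de_thresholds(config$lfc, config$alpha, config$moderation)

  # stage 1: per-cohort differential expression
  studies <- run("dge", list(
    a = read_expression_study(config$cohort_a$expression,
                              config$cohort_a$design,
                              config$cohort_a$id %||% "cohortA"),
    b = read_expression_study(config$cohort_b$expression,
                              config$cohort_b$design,
                              config$cohort_b$id %||% "cohortB")))
  degs <- list()
  cohort_counts <- list()
  for (side in c("a", "b")) {
    st <- studies[[side]]
    res <- run("dge", fit_differential(st, thr))
    dg <- call_degs(res, thr)
    write_tsv(res, file.path(outdir, sprintf("de_%s.tsv", st$cohort_id)))
    write_tsv(volcano_table(res),
              file.path(outdir, sprintf("volcano_%s.tsv", st$cohort_id)))
    write_tsv(dg, file.path(outdir, sprintf("degs_%s.tsv", st$cohort_id)))
    degs[[side]] <- dg
    cohort_counts[[st$cohort_id]] <- list(
      n_genes = nrow(st$matrix), n_samples = ncol(st$matrix),
      design = if (st$paired) "paired" else "unpaired",
      degs_total = nrow(dg),
      degs_up = sum(dg$direction == "up"),
      degs_down = sum(dg$direction == "down"))
    log_both("dge", "%s: %d DEGs (%d up / %d down) of %d genes",
             st$cohort_id, nrow(dg), sum(dg$direction == "up"),
             sum(dg$direction == "down"), nrow(st$matrix))
  }

  # stage 2: cross-cohort intersection
  venn <- run("set_ops", intersect_deg_lists(degs$a, degs$b))
  if (venn$both == 0L) {
    stage_error("set_ops",
                "the two cohorts share no DEGs; nothing to expand or score")
  }
  write_tsv(data.frame(gene = venn$overlap_genes,
                       discordant = venn$overlap_genes %in% venn$discordant),
            file.path(outdir, "overlap.tsv"))
  jsonlite::write_json(list(only_a = venn$only_a, only_b = venn$only_b,
                            both = venn$both,
                            discordant = venn$discordant),
                       file.path(outdir, "venn.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_both("set_ops", "overlap: %d genes (only A %d, only B %d)",
           venn$both, venn$only_a, venn$only_b)

  # stage 3: network expansion
  net <- run("network", read_interaction_network(config$network))
  expanded <- run("network",
                  expand_seed_set(net, venn$overlap_genes, k = config$k))
  write_expanded_set(expanded, file.path(outdir, "expanded.tsv"))
  log_both("network", "expanded %d seeds by %d interactors (k = %d) -> %d genes",
           length(expanded$seeds), nrow(expanded$added), expanded$k,
           length(expanded$genes))

  # stage 4: six-category enrichment scoring
  query <- expanded$genes
  measured <- sort(unique(c(rownames(studies$a$matrix),
                            rownames(studies$b$matrix))))
  collections <- list()
  ora <- list()
  for (cat in ANNOTATION_CATEGORIES) {
    coll <- run("enrichment", read_gmt(config$gmt[[cat]], cat))
    uni <- if (cat == "PID" && config$pid_universe == "measured")
      measured else NULL
    res <- run("enrichment", run_ora(query, coll, universe = uni))
    write_tsv(res, file.path(outdir, sprintf("enrichment_%s.tsv", cat)))
    collections[[cat]] <- coll
    ora[[cat]] <- res
    log_both("enrichment", "%s: %d/%d sets significant", cat,
             sum(res$significant), nrow(res))
  }
  scores <- run("enrichment",
                score_genes(query, ora, collections,
                            score_cutoff = config$score_cutoff))
  write_tsv(scores, file.path(outdir, "gene_scores.tsv"))
  risk <- select_risk_genes(scores, config$score_cutoff)
  write_tsv(data.frame(gene = risk,
                       score = scores$score[match(risk, scores$gene)]),
            file.path(outdir, "risk_genes.tsv"))
  score_dist <- as.list(table(factor(scores$score, levels = 0:6)))
  category_points <- lapply(setNames(ANNOTATION_CATEGORIES,
                                     ANNOTATION_CATEGORIES),
                            function(cat) sum(scores[[cat]]))
  jsonlite::write_json(list(score_distribution = score_dist,
                            category_points = category_points),
                       file.path(outdir, "score_distribution.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_both("enrichment", "%d risk genes at score >= %d",
           length(risk), config$score_cutoff)

  # stage 5: drug mapping
  dgi <- run("drug_mapping", read_dgi_table(config$dgi))
  report_drugs <- run("drug_mapping", map_drugs(risk, dgi))
  write_tsv(report_drugs$candidates, file.path(outdir, "candidates.tsv"))
  chord_export(report_drugs,
               sectors_path = file.path(outdir, "chord_sectors.tsv"),
               links_path = file.path(outdir, "chord_links.tsv"),
               json_path = file.path(outdir, "chord.json"))
  log_both("drug_mapping", "%d drugs across %d druggable risk genes",
           report_drugs$n_drugs, report_drugs$n_genes)

  # hash only the analysis-relevant settings, not file paths, so identical
  # analyses from different directories share a fingerprint
  cfg_for_hash <- list(lfc = config$lfc, alpha = config$alpha,
                       moderation = config$moderation, k = config$k,
                       score_cutoff = config$score_cutoff,
                       pid_universe = config$pid_universe,
                       seed = config$seed)
  report <- list(
    package_version = as.character(utils::packageVersion("dfurepo")),
    config_hash = fnv1a32(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE)),
    thresholds = list(lfc = config$lfc, alpha = config$alpha,
                      moderation = config$moderation, k = config$k,
                      score_cutoff = config$score_cutoff),
    cohorts = cohort_counts,
    overlap = list(count = venn$both, only_a = venn$only_a,
                   only_b = venn$only_b,
                   n_discordant = length(venn$discordant)),
    expansion = list(k = expanded$k, n_seeds = length(expanded$seeds),
                     n_added = nrow(expanded$added),
                     n_total = length(expanded$genes)),
    enrichment = list(
      per_category = lapply(setNames(ANNOTATION_CATEGORIES,
                                     ANNOTATION_CATEGORIES), function(cat) {
        list(n_sets = nrow(ora[[cat]]),
             n_significant = sum(ora[[cat]]$significant),
             gene_points = category_points[[cat]])
      }),
      score_distribution = score_dist),
    risk = list(score_cutoff = config$score_cutoff, n_risk = length(risk)),
    drugs = list(n_druggable = report_drugs$n_genes,
                 n_drugs = report_drugs$n_drugs,
                 n_candidate_rows = nrow(report_drugs$candidates))
  )

  # internal consistency before the report is written
  for (co in report$cohorts) {
    stopifnot(co$degs_up + co$degs_down == co$degs_total)
  }
  stopifnot(report$expansion$n_total ==
              report$overlap$count + report$expansion$n_added,
            report$drugs$n_druggable <= report$risk$n_risk)

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_both("pipeline", "report.json written")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
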