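#' Read a scored interaction network
#'
#' Reads a STRING-style edge list TSV (`gene_a`, `gene_b`,
#' `combined_score` with integer scores in \[0, 1000\]). Self-loops are
#' dropped with a message; duplicate unordered pairs are collapsed keeping
#' the maximum score.
#'
#' @param path Edge-list TSV path, or a `data.frame` with the same columns.
#' @return A `data.frame` of class `InteractionNetwork`.
#' @export
read_interaction_network <- function(path) {
  net <- if (is.data.frame(path)) path else read_tsv(path)
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% names(net))) {
    abort("network needs columns gene_a, gene_b, combined_score")
  }
  net <- net[, need]
  net$combined_score <- as.integer(net$combined_score)
  if (any(net$combined_score < 0 | net$combined_score > 1000, na.rm = TRUE)) {
    abort("combined_score must lie in [0, 1000]")
  }
  loops <- net$gene_a == net$gene_b
  if (any(loops)) {
    log_line("network", "dropping %d self-loop edge(s)", sum(loops))
    net <- net[!loops, , drop = FALSE]
  }
  key <- ifelse(net$gene_a < net$gene_b,
                paste(net$gene_a, net$gene_b, sep = "\r"),
                paste(net$gene_b, net$gene_a, sep = "\r"))
  if (anyDuplicated(key)) {
    log_line("network", "collapsing %d duplicate edge(s), keeping max score",
             sum(duplicated(key)))
    ord <- order(key, -net$combined_score)
    net <- net[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  }
  rownames(net) <- NULL
  class(net) <- c("InteractionNetwork", "data.frame")
  net
}

#' Expand a seed gene set with its top-scoring interactors
#'
#' Ranks every non-seed gene that touches the seed set by its best (maximum)
#' combined score to any seed, descending, with ties broken by gene symbol
#' ascending, and adds the top `k` to the seed set. Seed-seed edges are
#' ignored for ranking. This reproduces the "threshold of 50 interactions"
#' expansion step: a 31-gene seed set with at least 50 scored non-seed
#' neighbors grows to exactly 81 genes at the default `k = 50`.
#'
#' @param net An edge list (path, `data.frame`, or
#'   [read_interaction_network()] output).
#' @param seeds Non-empty character vector of seed genes.
#' @param k Number of new interactor genes to add (default 50).
#' @return A list of class `ExpandedGeneSet` with `seeds`, `added`
#'   (`data.frame` `gene`, `best_score`, `anchor_seed` in rank order), `k`
#'   and `genes` (the union, seeds first then added in rank order).
#' @export
#'
#' @examples
#' net <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("N1", "N2", "N2"),
#'                   combined_score = c(900L, 800L, 950L))
#' expand_seed_set(net, seeds = c("A", "B"), k = 1)
expand_seed_set <- function(net, seeds, k = 50L) {
  if (!length(seeds)) abort("`seeds` must be non-empty")
  if (k < 0) abort("`k` must be >= 0")
  if (!inherits(net, "InteractionNetwork")) net <- read_interaction_network(net)
  seeds <- sort(unique(seeds))

  a_seed <- net$gene_a %in% seeds
  b_seed <- net$gene_b %in% seeds
  cross <- xor(a_seed, b_seed)
  cand_gene <- ifelse(a_seed[cross], net$gene_b[cross], net$gene_a[cross])
  cand_anchor <- ifelse(a_seed[cross], net$gene_a[cross], net$gene_b[cross])
  cand_score <- net$combined_score[cross]

  if (!length(cand_gene) && k > 0L) {
    warnf("no scored seed-to-candidate edges in the network; returning seeds only")
  }

  if (length(cand_gene)) {
    # per candidate: max score; anchor = seed achieving it (smallest symbol on ties)
    ord <- order(cand_gene, -cand_score, cand_anchor)
    first <- !duplicated(cand_gene[ord])
    best <- data.frame(gene = cand_gene[ord][first],
                       best_score = cand_score[ord][first],
                       anchor_seed = cand_anchor[ord][first],
                       stringsAsFactors = FALSE)
    best <- best[order(-best$best_score, best$gene), , drop = FALSE]
  } else {
    best <- data.frame(gene = character(), best_score = integer(),
                       anchor_seed = character(), stringsAsFactors = FALSE)
  }

  if (nrow(best) < k && nrow(best) > 0L) {
    warnf("only %d candidate interactor(s) available for k = %d; taking all",
          nrow(best), k)
  }
  added <- head(best, k)
  rownames(added) <- NULL
  structure(
    list(seeds = seeds, added = added, k = as.integer(k),
         genes = c(seeds, added$gene)),
    class = "ExpandedGeneSet"
  )
}

#' @export
print.ExpandedGeneSet <- function(x, ...) {
  cat(sprintf("ExpandedGeneSet: %d seeds + %d added (k = %d) = %d genes\n",
              length(x$seeds), nrow(x$added), x$k, length(x$genes)))
  invisible(x)
}

#' Export an expanded gene set with provenance
#'
#' @param expanded An [expand_seed_set()] result.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_expanded_set <- function(expanded, path) {
  added <- expanded$added
  df <- data.frame(gene = c(expanded$seeds, added$gene),
                   role = rep(c("seed", "added"),
                              c(length(expanded$seeds), nrow(added))),
                   best_score = c(rep(NA_integer_, length(expanded$seeds)),
                                  added$best_score),
                   anchor_seed = c(rep(NA_character_, length(expanded$seeds)),
                                   added$anchor_seed),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
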