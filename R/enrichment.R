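#' Gene-set collection
#'
#' A named collection of gene sets belonging to one of the six annotation
#' categories used by the prioritization score ([annotation_categories()]).
#'
#' @param category One of `"KMP"`, `"PID"`, `"KEGG"`, `"BP"`, `"CC"`, `"MF"`.
#' @param sets Named list of character vectors (set id -> member genes).
#'   All sets must be non-empty; singleton sets are accepted with a message.
#' @param descriptions Optional named character vector of set descriptions.
#' @return A list of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(category, sets, descriptions = NULL) {
  if (!category %in% ANNOTATION_CATEGORIES) {
    abort("category must be one of %s",
          paste(ANNOTATION_CATEGORIES, collapse = ", "))
  }
  if (length(sets) && is.null(names(sets))) abort("`sets` must be named")
  sizes <- lengths(sets)
  if (any(sizes == 0L)) abort("all gene sets must be non-empty")
  if (any(sizes == 1L)) {
    log_line("gmt", "%s: %d singleton set(s) accepted", category, sum(sizes == 1L))
  }
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("na", length(sets)), names(sets))
  }
  structure(list(category = category, sets = sets,
                 descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection '%s': %d sets, %d annotated genes\n",
              x$category, length(x$sets), length(collection_universe(x))))
  invisible(x)
}

#' Genes annotated anywhere in a collection
#' @param collection A [gene_set_collection()].
#' @return Sorted character vector (the collection's annotation universe).
#' @export
collection_universe <- function(collection) {
  sort(unique(unlist(collection$sets, use.names = FALSE)))
}

#' Read a GMT file into a gene-set collection
#'
#' Standard GMT: one set per line, tab-separated
#' `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. An empty file is a
#' valid empty collection.
#'
#' @param path GMT file path.
#' @param category Annotation category for the collection.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, category) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) abort("malformed GMT line (need >= 3 fields): %s",
                                  substr(ln, 1, 60))
    sets[[parts[1]]] <- parts[-(1:2)]
    desc[parts[1]] <- parts[2]
  }
  gene_set_collection(category, sets, desc)
}

#' Write a gene-set collection to GMT
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(sid) {
    paste(c(sid, collection$descriptions[[sid]], collection$sets[[sid]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value `P(X >= k)` for
#' `X ~ Hypergeometric(N, K_set, n)`: drawing a query of size `n` from a
#' universe of `N` genes of which `K_set` are in the set, the probability of
#' seeing `k` or more set members. Summed in log space for numerical
#' stability.
#'
#' @param N Universe size.
#' @param K_set Gene-set size.
#' @param n Query size.
#' @param k Observed overlap.
#' @return The upper-tail probability in (0, 1\].
#' @export
#'
#' @examples
#' hypergeom_tail(N = 20, K_set = 5, n = 5, k = 5)  # 1 / choose(20, 5)
hypergeom_tail <- function(N, K_set, n, k) {
  if (K_set > N || n > N || k > min(K_set, n) || k < 0 ||
      N < 0 || K_set < 0 || n < 0) {
    abort("infeasible hypergeometric arguments (N=%s, K_set=%s, n=%s, k=%s)",
          N, K_set, n, k)
  }
  if (k == 0L) return(1)
  i <- seq.int(k, min(K_set, n))
  lp <- lchoose(K_set, i) + lchoose(N - K_set, n - i) - lchoose(N, n)
  min(1, exp(logsumexp(lp)))
}

#' Benjamini-Hochberg step-up q-values
#'
#' Sorts the p-values ascending, forms `p_(i) * m / i`, enforces
#' monotonicity from the largest rank down (`q_(i) = min_{j >= i} p_(j)*m/j`),
#' caps at 1 and returns the q-values in the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
#'
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  q
}

#' Over-representation analysis of a query against a collection
#'
#' One hypergeometric upper-tail test per set, against the collection's
#' annotation universe by default (WebGestalt-style annotated reference) or
#' an explicit universe. Within-category multiple testing uses
#' Benjamini-Hochberg. Significance follows the category's rule: the PID
#' category is collapsed to a single gene list and judged on the raw
#' p-value (`p < 0.05`); every other category uses the BH q-value
#' (`q < 0.05`). Both comparisons are strict.
#'
#' @param query Non-empty character vector of query genes.
#' @param collection A [gene_set_collection()].
#' @param universe Optional explicit universe; default: all genes annotated
#'   in the collection.
#' @param q_cutoff,p_cutoff Significance cutoffs (defaults 0.05).
#' @return A `data.frame` of class `EnrichmentResult` with columns `set_id`,
#'   `k`, `n`, `K_set`, `N`, `p_value`, `q_value`, `significant`, ordered by
#'   p-value; attribute `category`.
#' @export
run_ora <- function(query, collection, universe = NULL,
                    q_cutoff = 0.05, p_cutoff = 0.05) {
  if (!length(query)) abort("`query` must be non-empty")
  stopifnot(inherits(collection, "GeneSetCollection"))
  query <- unique(query)
  sets <- collection$sets
  if (collection$category == "PID" && length(sets) > 1L) {
    # the PID annotation is a single curated gene list; collapse to one set
    sets <- list(PID = sort(unique(unlist(sets, use.names = FALSE))))
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(universe)
    outside <- lapply(sets, setdiff, y = universe)
    if (any(lengths(outside) > 0)) {
      abort("%s: gene set members outside the supplied universe",
            collection$category)
    }
  }
  N <- length(universe)
  q_in <- intersect(query, universe)
  n <- length(q_in)
  if (n == 0L && length(sets)) {
    warnf("%s: query does not intersect the universe; all p = 1",
          collection$category)
  }
  if (!length(sets)) {
    res <- data.frame(set_id = character(), k = integer(), n = integer(),
                      K_set = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical())
  } else {
    k <- vapply(sets, function(s) length(intersect(q_in, s)), integer(1))
    K_set <- lengths(sets)
    p <- vapply(seq_along(sets), function(i) {
      if (N == 0L) 1 else hypergeom_tail(N, K_set[i], n, k[i])
    }, numeric(1))
    q <- bh_fdr(p)
    sig <- if (collection$category == "PID") p < p_cutoff else q < q_cutoff
    res <- data.frame(set_id = names(sets), k = k, n = n, K_set = K_set,
                      N = N, p_value = p, q_value = q, significant = sig,
                      stringsAsFactors = FALSE)
    res <- res[order(res$p_value, res$set_id), ]
    rownames(res) <- NULL
  }
  attr(res, "category") <- collection$category
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Score query genes across the six annotation categories
#'
#' A gene earns one point per category in which it belongs to at least one
#' significant set (for PID: the single list-level test must be significant
#' and the gene must be in the PID list). The score is the sum over the six
#' categories (0-6); genes scoring at or above `score_cutoff` are flagged
#' as biological risk genes. A gene absent from a category's annotation
#' universe simply cannot earn that category's point.
#'
#' @param query Character vector of query genes (the expanded DEG set).
#' @param ora_results Named list of six [run_ora()] tables, one per
#'   category.
#' @param collections Named list of the six [gene_set_collection()]s.
#' @param score_cutoff Risk-gene cutoff, inclusive (default 2).
#' @return A `data.frame` of class `GeneScoreTable`: `gene`, one 0/1 column
#'   per category, `score`, `is_risk_gene`; rows ordered by score
#'   descending, gene ascending.
#' @export
score_genes <- function(query, ora_results, collections, score_cutoff = 2L) {
  if (!setequal(names(ora_results), ANNOTATION_CATEGORIES) ||
      !setequal(names(collections), ANNOTATION_CATEGORIES)) {
    abort("ora_results and collections must cover exactly the six categories")
  }
  query <- unique(query)
  pts <- matrix(0L, length(query), length(ANNOTATION_CATEGORIES),
                dimnames = list(query, ANNOTATION_CATEGORIES))
  for (cat in ANNOTATION_CATEGORIES) {
    res <- ora_results[[cat]]
    coll <- collections[[cat]]
    sig_ids <- res$set_id[res$significant]
    if (!length(sig_ids)) next
    if (cat == "PID") {
      members <- unique(unlist(coll$sets, use.names = FALSE))
    } else {
      members <- unique(unlist(coll$sets[sig_ids], use.names = FALSE))
    }
    pts[intersect(query, members), cat] <- 1L
  }
  score <- as.integer(rowSums(pts))
  out <- data.frame(gene = query, pts, score = score,
                    is_risk_gene = score >= score_cutoff,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(-out$score, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("GeneScoreTable", "data.frame")
  out
}

#' Select biological risk genes
#'
#' Genes whose six-category annotation score meets the inclusive cutoff,
#' ordered by score descending then symbol ascending.
#'
#' @param scores A [score_genes()] table.
#' @param score_cutoff Inclusive cutoff (default 2).
#' @return Character vector of risk-gene symbols in rank order.
#' @export
select_risk_genes <- function(scores, score_cutoff = 2L) {
  keep <- scores[scores$score >= score_cutoff, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$gene), ]
  keep$gene
}
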