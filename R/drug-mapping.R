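#' Read a drug-gene interaction snapshot
#'
#' DGIdb-style TSV with columns `drug_name`, `gene`, `interaction_type`
#' (possibly empty) and `approved` (`yes`/`no`). Duplicate drug-gene pairs
#' (drug names compared case-insensitively) are collapsed: interaction types
#' are unioned (pipe-separated) and the pair is approved if any of its rows
#' was.
#'
#' @param path TSV path or a `data.frame` with the same columns.
#' @return A `data.frame` of class `DrugGeneInteractionTable`.
#' @export
read_dgi_table <- function(path) {
  dgi <- if (is.data.frame(path)) path else read_tsv(path, colClasses = "character")
  need <- c("drug_name", "gene", "interaction_type", "approved")
  if (!all(need %in% names(dgi))) {
    abort("drug table needs columns drug_name, gene, interaction_type, approved")
  }
  dgi <- dgi[, need]
  dgi$interaction_type[is.na(dgi$interaction_type)] <- ""
  dgi$interaction_type <- trimws(dgi$interaction_type)
  if (any(!nzchar(dgi$drug_name)) || any(!nzchar(dgi$gene))) {
    abort("drug_name and gene must be non-empty")
  }
  if (is.logical(dgi$approved)) dgi$approved <- ifelse(dgi$approved, "yes", "no")
  if (!all(dgi$approved %in% c("yes", "no"))) {
    abort("`approved` must be 'yes' or 'no'")
  }
  key <- paste(toupper(dgi$drug_name), dgi$gene, sep = "\r")
  if (anyDuplicated(key)) {
    log_line("drugs", "collapsing %d duplicate drug-gene row(s)",
             sum(duplicated(key)))
    parts <- split(seq_len(nrow(dgi)), key)
    dgi <- do.call(rbind, lapply(parts, function(idx) {
      types <- unique(dgi$interaction_type[idx])
      types <- types[nzchar(types)]
      data.frame(drug_name = dgi$drug_name[idx[1]],
                 gene = dgi$gene[idx[1]],
                 interaction_type = paste(types, collapse = "|"),
                 approved = if (any(dgi$approved[idx] == "yes")) "yes" else "no",
                 stringsAsFactors = FALSE)
    }))
  }
  dgi <- dgi[order(dgi$gene, dgi$drug_name), ]
  rownames(dgi) <- NULL
  class(dgi) <- c("DrugGeneInteractionTable", "data.frame")
  dgi
}

#' Map risk genes to candidate repositioning drugs
#'
#' Joins the risk-gene list to the drug-gene interaction snapshot and keeps
#' rows for risk genes whose drug is approved (when `approved_only`) and has
#' a defined, non-empty interaction type (when `require_interaction_type`) -
#' the "FDA-approved drugs with clear interaction types" rule. Output is
#' deterministic: gene ascending, then drug ascending.
#'
#' @param risk_genes Non-empty character vector.
#' @param dgi A [read_dgi_table()] table (or path / raw `data.frame`).
#' @param approved_only Keep only approved drugs. Default `TRUE`.
#' @param require_interaction_type Keep only rows with a non-empty
#'   interaction type. Default `TRUE`.
#' @return A list of class `CandidateReport`: `candidates` (`data.frame`
#'   `drug`, `gene`, `interaction_type`), `druggable_genes`, `n_drugs`,
#'   `n_genes`.
#' @export
#'
#' @examples
#' dgi <- data.frame(drug_name = c("drugA", "drugB"), gene = c("G1", "G2"),
#'                   interaction_type = c("inhibitor", "agonist"),
#'                   approved = c("yes", "no"))
#' map_drugs(c("G1", "G2"), dgi)
map_drugs <- function(risk_genes, dgi, approved_only = TRUE,
                      require_interaction_type = TRUE) {
  if (!length(risk_genes)) abort("`risk_genes` must be non-empty")
  if (!inherits(dgi, "DrugGeneInteractionTable")) dgi <- read_dgi_table(dgi)
  if (!nrow(dgi)) warnf("empty drug-gene interaction table")
  keep <- dgi$gene %in% risk_genes
  if (approved_only) keep <- keep & dgi$approved == "yes"
  if (require_interaction_type) keep <- keep & nzchar(dgi$interaction_type)
  cand <- dgi[keep, c("drug_name", "gene", "interaction_type"), drop = FALSE]
  names(cand)[1] <- "drug"
  cand <- cand[order(cand$gene, cand$drug), ]
  rownames(cand) <- NULL
  structure(
    list(candidates = cand,
         druggable_genes = sort(unique(cand$gene)),
         n_drugs = length(unique(toupper(cand$drug))),
         n_genes = length(unique(cand$gene))),
    class = "CandidateReport"
  )
}

#' @export
print.CandidateReport <- function(x, ...) {
  cat(sprintf("CandidateReport: %d candidate drug(s) across %d druggable gene(s), %d rows\n",
              x$n_drugs, x$n_genes, nrow(x$candidates)))
  invisible(x)
}

#' Export chord-diagram data for the gene-drug map
#'
#' Writes the sector list (genes and drugs) and the link list (one link per
#' candidate row) as TSV plus a combined JSON, suitable for any chord
#' renderer. Lossless with respect to the candidate rows; empty reports
#' yield valid empty files.
#'
#' @param report A [map_drugs()] report.
#' @param sectors_path,links_path,json_path Output paths (any may be `NULL`
#'   to skip).
#' @return Invisibly, a list with the `sectors` and `links` data frames.
#' @export
chord_export <- function(report, sectors_path = NULL, links_path = NULL,
                         json_path = NULL) {
  stopifnot(inherits(report, "CandidateReport"))
  cand <- report$candidates
  genes <- sort(unique(cand$gene))
  drugs <- sort(unique(cand$drug))
  sectors <- data.frame(name = c(genes, drugs),
                        type = rep(c("gene", "drug"),
                                   c(length(genes), length(drugs))),
                        stringsAsFactors = FALSE)
  links <- data.frame(gene = cand$gene, drug = cand$drug,
                      interaction_type = cand$interaction_type,
                      stringsAsFactors = FALSE)
  if (!is.null(sectors_path)) write_tsv(sectors, sectors_path)
  if (!is.null(links_path)) write_tsv(links, links_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(sectors = sectors, links = links), json_path,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(list(sectors = sectors, links = links))
}
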