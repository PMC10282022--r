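#' Expression study container
#'
#' Bundles a pre-normalized log2 expression matrix (genes x samples) with its
#' sample design table. The design distinguishes case from control samples
#' and, for paired cohorts (e.g. ulcer and adjacent normal tissue from the
#' same patient), records the pair each sample belongs to.
#'
#' @param matrix Numeric matrix of log2 intensities, genes in rows (rownames
#'   are gene symbols), samples in columns (colnames are sample IDs).
#' @param design `data.frame` with columns `sample`, `group` (one of
#'   `"case"`, `"control"`) and optionally `pair_id` (`NA` for unpaired).
#' @param cohort_id Single string labelling the cohort.
#'
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `matrix`, `design`, `cohort_id` and `paired` (logical).
#' @export
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("A", "B", "C"), paste0("S", 1:4)))
#' d <- data.frame(sample = paste0("S", 1:4),
#'                 group = c("case", "case", "control", "control"),
#'                 pair_id = NA)
#' expression_study(m, d, "demo")
expression_study <- function(matrix, design, cohort_id = "cohort") {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix of log2 intensities")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    abort("`matrix` needs gene rownames and sample colnames")
  }
  check_gene_symbols(rownames(matrix))
  if (anyNA(matrix)) {
    abort("expression matrix contains missing values; inputs must be complete")
  }
  need <- c("sample", "group")
  if (!all(need %in% names(design))) {
    abort("design table must have columns `sample` and `group`")
  }
  if (!"pair_id" %in% names(design)) design$pair_id <- NA
  design <- design[, c("sample", "group", "pair_id")]
  design$sample <- as.character(design$sample)
  design$group <- as.character(design$group)
  if (!setequal(design$sample, colnames(matrix)) ||
      anyDuplicated(design$sample)) {
    abort("design samples must match matrix columns exactly (no duplicates)")
  }
  if (!all(design$group %in% c("case", "control"))) {
    abort("`group` must be 'case' or 'control'")
  }
  n_case <- sum(design$group == "case")
  n_ctrl <- sum(design$group == "control")
  if (n_case < 2L || n_ctrl < 2L) {
    abort("need at least 2 samples per group (got %d case, %d control)",
          n_case, n_ctrl)
  }
  paired <- any(!is.na(design$pair_id))
  if (paired) {
    if (anyNA(design$pair_id)) {
      abort("paired design requires a pair_id for every sample")
    }
    design$pair_id <- as.character(design$pair_id)
    tab <- table(design$pair_id, design$group)
    if (!all(tab == 1L)) {
      abort("every pair_id must appear exactly once per group")
    }
  }
  structure(
    list(matrix = matrix, design = design,
         cohort_id = as.character(cohort_id)[1], paired = paired),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy '%s': %d genes x %d samples (%s design, %d case / %d control)\n",
              x$cohort_id, nrow(x$matrix), ncol(x$matrix),
              if (x$paired) "paired" else "unpaired",
              sum(x$design$group == "case"),
              sum(x$design$group == "control")))
  invisible(x)
}

#' Write an expression study to a TSV pair
#'
#' Emits the expression matrix as a TSV whose first column is `gene` and the
#' design as a companion TSV (`sample`, `group`, `pair_id`). Identical inputs
#' produce byte-identical files.
#'
#' @param study An [expression_study()] object.
#' @param expr_path,design_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_expression_study <- function(study, expr_path, design_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, expr_path)
  des <- study$design
  des$pair_id <- ifelse(is.na(des$pair_id), "NA", as.character(des$pair_id))
  write_tsv(des, design_path)
  invisible(c(expr_path, design_path))
}

#' Read an expression study from a TSV pair
#'
#' @param expr_path TSV with first column `gene`, remaining columns samples.
#' @param design_path TSV with columns `sample`, `group`, `pair_id`
#'   (`NA` allowed for unpaired designs).
#' @param cohort_id Cohort label; defaults to the expression file name.
#' @return An [expression_study()] object.
#' @export
read_expression_study <- function(expr_path, design_path,
                                  cohort_id = NULL) {
  if (is.null(cohort_id)) {
    cohort_id <- sub("\\.[^.]*$", "", basename(expr_path))
  }
  df <- read_tsv(expr_path)
  if (names(df)[1] != "gene") abort("expression TSV must start with a 'gene' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  des <- read_tsv(design_path, colClasses = "character")
  des$pair_id[des$pair_id %in% c("NA", "")] <- NA
  expression_study(m, des, cohort_id)
}
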