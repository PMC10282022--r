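#' Intersect two DEG lists into a Venn summary
#'
#' Exact, case-sensitive set intersection of the two cohorts' DEG symbol
#' lists. Direction of regulation is ignored for membership (a gene up in
#' one cohort and down in the other still counts); when per-cohort
#' directions are supplied, direction-discordant overlap genes are flagged
#' in the output rather than dropped.
#'
#' @param a,b Character vectors of unique gene symbols, or `data.frame`s
#'   from [call_degs()] (column `gene`, optionally `direction`).
#' @return A list of class `VennSummary` with fields `only_a`, `only_b`,
#'   `both` (counts), `overlap_genes` (lexicographically ordered) and
#'   `discordant` (overlap genes whose directions disagree across cohorts,
#'   when directions were available).
#' @export
#'
#' @examples
#' intersect_deg_lists(c("X", "Y", "Z"), c("Y", "Z", "W"))
intersect_deg_lists <- function(a, b) {
  dir_a <- dir_b <- NULL
  if (is.data.frame(a)) { dir_a <- setNames(a$direction, a$gene); a <- a$gene }
  if (is.data.frame(b)) { dir_b <- setNames(b$direction, b$gene); b <- b$gene }
  if (anyDuplicated(a)) abort("duplicate gene symbols in list `a`")
  if (anyDuplicated(b)) abort("duplicate gene symbols in list `b`")
  overlap <- sort(intersect(a, b))
  discordant <- character()
  if (!is.null(dir_a) && !is.null(dir_b) && length(overlap)) {
    discordant <- overlap[dir_a[overlap] != dir_b[overlap]]
  }
  structure(
    list(only_a = length(setdiff(a, b)),
         only_b = length(setdiff(b, a)),
         both = length(overlap),
         overlap_genes = overlap,
         discordant = discordant),
    class = "VennSummary"
  )
}

#' @export
print.VennSummary <- function(x, ...) {
  cat(sprintf("VennSummary: only A = %d, only B = %d, both = %d\n",
              x$only_a, x$only_b, x$both))
  if (length(x$discordant)) {
    cat("direction-discordant overlap genes:",
        paste(x$discordant, collapse = ", "), "\n")
  }
  invisible(x)
}
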