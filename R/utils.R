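#' @keywords internal
"_PACKAGE"

#' @importFrom stats pt var rnorm setNames
#' @importFrom utils read.delim write.table head
NULL

# The six functional annotation categories used by the prioritization score:
# knockout-mouse phenotype (Mammalian Phenotype Ontology), primary
# immunodeficiency gene list, KEGG pathways, and the three Gene Ontology
# branches (biological process, cellular component, molecular function).
ANNOTATION_CATEGORIES <- c("KMP", "PID", "KEGG", "BP", "CC", "MF")

#' Annotation category names
#'
#' Returns the six functional annotation categories recognised by the
#' prioritization score, in canonical order: `"KMP"`, `"PID"`, `"KEGG"`,
#' `"BP"`, `"CC"`, `"MF"`.
#'
#' @return Character vector of length six.
#' @export
annotation_categories <- function() ANNOTATION_CATEGORIES

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# one structured log line per event, to stderr (collected by the CLI runner)
log_line <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Tab-separated writers with fixed conventions so identical inputs give
# byte-identical files (determinism contract of the generators).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# log-sum-exp over a numeric vector, guarding the empty and -Inf cases
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# 32-bit FNV-1a over a character scalar; used for the run-report config hash.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # XOR only touches the low byte since b < 256; keeps h a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, split to stay
    # inside exact double-precision integer range
    hi <- floor(h / 65536)
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

# validate a seed and return it as integer; seeds fully determine generator
# output, so they must be whole numbers
check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed) ||
      seed != trunc(seed)) {
    abort("`seed` must be a single whole number, got %s",
          paste(format(seed), collapse = ","))
  }
  as.integer(seed)
}

check_gene_symbols <- function(genes, what = "gene") {
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    abort("duplicate %s symbols: %s", what,
          paste(head(dups, 5L), collapse = ", "))
  }
  if (any(!nzchar(genes)) || anyNA(genes)) {
    abort("empty or missing %s symbols are not allowed", what)
  }
  invisible(genes)
}
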