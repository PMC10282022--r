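# Small fixture builders shared across test files.

# A study whose per-pair case-minus-control differences are given exactly
# (zero noise elsewhere); gene_diffs is a named list gene -> numeric vector.
paired_study_from_diffs <- function(gene_diffs, baseline = 7) {
  n <- length(gene_diffs[[1]])
  genes <- names(gene_diffs)
  ctrl <- matrix(baseline, length(genes), n,
                 dimnames = list(genes, sprintf("ctrl_%02d", 1:n)))
  case <- ctrl + do.call(rbind, gene_diffs)
  colnames(case) <- sprintf("case_%02d", 1:n)
  m <- cbind(case, ctrl)
  des <- data.frame(sample = colnames(m),
                    group = rep(c("case", "control"), each = n),
                    pair_id = rep(sprintf("P%02d", 1:n), 2))
  expression_study(m, des, "diff-fixture")
}

# An unpaired study from explicit case/control matrices
unpaired_study <- function(case, ctrl) {
  colnames(case) <- sprintf("case_%02d", seq_len(ncol(case)))
  colnames(ctrl) <- sprintf("ctrl_%02d", seq_len(ncol(ctrl)))
  m <- cbind(case, ctrl)
  des <- data.frame(sample = colnames(m),
                    group = rep(c("case", "control"),
                                c(ncol(case), ncol(ctrl))),
                    pair_id = NA)
  expression_study(m, des, "unpaired-fixture")
}

# Independent brute-force hypergeometric upper tail using plain choose()
hyper_tail_bruteforce <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Independent hand step-up BH: q_(i) = min_{j >= i} p_(j) * m / j
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- sapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))))
  out <- numeric(m)
  out[o] <- q
  out
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE, recursive = TRUE))
  setNames(as.character(tools::md5sum(files)), basename(files))
}
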