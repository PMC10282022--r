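#' Differential-expression thresholds
#'
#' DEG calling uses the fold-change / significance rule
#' \eqn{|logFC| > \tau} (strict) and \eqn{p \le \alpha}, with defaults
#' \eqn{\tau = 2} (log2 units) and \eqn{\alpha = 0.05} on the raw
#' (uncorrected) p-value.
#'
#' @param lfc Log2 fold-change cutoff, `>= 0`. Default 2.
#' @param alpha Two-sided p-value cutoff in (0, 1). Default 0.05.
#' @param moderation `"eBayes"` (default) for empirical-Bayes variance
#'   moderation, `"ordinary"` for textbook t-statistics.
#' @return A list of class `DEThresholds`.
#' @export
de_thresholds <- function(lfc = 2, alpha = 0.05,
                          moderation = c("eBayes", "ordinary")) {
  moderation <- match.arg(moderation)
  if (lfc < 0) abort("`lfc` must be >= 0")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  structure(list(lfc = lfc, alpha = alpha, moderation = moderation),
            class = "DEThresholds")
}

# Invert the trigamma function by Newton iteration on 1/trigamma, which is
# nearly linear; mirrors the classic moderated-t hyperparameter fit.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Estimate empirical-Bayes variance-moderation hyperparameters
#'
#' Fits a scaled inverse-chi-square prior to per-gene residual variances by
#' the method of moments on `log(s_sq)`: the mean and variance of the log
#' variances are matched to their digamma/trigamma expectations under the
#' hierarchical model, giving the prior degrees of freedom `d0` and prior
#' variance `s0_sq`. When the spread of the log variances is at or below the
#' pure sampling floor `trigamma(df/2)`, the prior is degenerate:
#' `d0 = Inf` and every posterior variance equals the geometric-mean-based
#' `s0_sq`.
#'
#' @param s_sq Per-gene residual variances (`>= 0`).
#' @param df Residual degrees of freedom (single value, `>= 1`).
#' @return A list with `d0`, `s0_sq` and `post_var` (the posterior variances
#'   `(d0*s0_sq + df*s_sq) / (d0 + df)`).
#' @export
#'
#' @examples
#' moderate_variances(c(1, 2, 0.5, 1.5), df = 4)
moderate_variances <- function(s_sq, df) {
  if (any(s_sq < 0, na.rm = TRUE)) abort("residual variances must be >= 0")
  if (df < 1) abort("residual df must be >= 1")
  usable <- s_sq[is.finite(s_sq) & s_sq > 0]
  if (length(s_sq) < 2L || length(usable) < 2L) {
    warnf("fewer than 2 positive residual variances; moderation not estimable, using ordinary variances")
    return(list(d0 = 0, s0_sq = NA_real_, post_var = s_sq))
  }
  z <- log(usable)
  e_mean <- mean(z)
  e_var <- var(z)
  floor_var <- trigamma(df / 2)
  if (e_var <= floor_var) {
    # log-variance spread explainable by sampling alone: infinitely strong prior
    d0 <- Inf
    s0_sq <- exp(e_mean - digamma(df / 2) + log(df / 2))
    post <- rep(s0_sq, length(s_sq))
  } else {
    d0 <- 2 * trigamma_inverse(e_var - floor_var)
    s0_sq <- exp(e_mean - digamma(df / 2) + log(df / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    post <- posterior_variances(s_sq, df, d0, s0_sq)
  }
  list(d0 = d0, s0_sq = s0_sq, post_var = post)
}

#' Posterior (moderated) variances
#'
#' Convex combination of the prior variance and each gene's sample variance,
#' weighted by their degrees of freedom:
#' `(d0*s0_sq + df*s_sq) / (d0 + df)`. `d0 = 0` returns the sample
#' variances, `d0 = Inf` returns `s0_sq` for every gene.
#'
#' @param s_sq Per-gene residual variances.
#' @param df Residual degrees of freedom.
#' @param d0 Prior degrees of freedom (`>= 0`, may be `Inf`).
#' @param s0_sq Prior variance (`> 0`).
#' @return Numeric vector of posterior variances.
#' @export
posterior_variances <- function(s_sq, df, d0, s0_sq) {
  if (is.infinite(d0)) return(rep(s0_sq, length(s_sq)))
  if (d0 < 0) abort("`d0` must be >= 0")
  (d0 * s0_sq + df * s_sq) / (d0 + df)
}

#' Per-cohort differential expression
#'
#' Fits the cohort's linear contrast gene by gene. Paired designs use the
#' within-pair case-minus-control differences: the log fold change is the
#' mean difference and the t-statistic is a one-sample t on the differences
#' with `n_pairs - 1` degrees of freedom. Unpaired designs use the
#' case-minus-control mean difference with a pooled-variance two-sample t on
#' `n_case + n_control - 2` degrees of freedom. With
#' `moderation = "eBayes"` the residual variances are shrunk toward an
#' empirically estimated prior ([moderate_variances()]) and the degrees of
#' freedom increase by the prior `d0` before two-sided p-values are taken
#' from the t distribution.
#'
#' @param study An [expression_study()].
#' @param thresholds A [de_thresholds()] object (controls moderation and the
#'   DEG rule recorded in the table).
#' @return A `data.frame` of class `DEResultTable` with columns `gene`,
#'   `logFC`, `t_stat`, `p_value`, `direction` (`up`/`down`/`none`) and
#'   `is_deg`, plus attributes `d0`, `s0_sq`, `df_residual`, `cohort_id`.
#' @export
#'
#' @examples
#' sim <- generate_cohort(50, list(type = "unpaired", n_case = 3, n_control = 3),
#'                        planted = data.frame(gene = "G0001", logfc = 3),
#'                        noise_sd = 0.2, seed = 7)
#' head(fit_differential(sim$study, de_thresholds()))
fit_differential <- function(study, thresholds = de_thresholds()) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (!inherits(thresholds, "DEThresholds")) {
    abort("`thresholds` must come from de_thresholds()")
  }
  m <- study$matrix
  des <- study$design
  case_ids <- des$sample[des$group == "case"]
  ctrl_ids <- des$sample[des$group == "control"]

  if (study$paired) {
    # align case and control columns by pair_id
    pair_of <- setNames(des$pair_id, des$sample)
    case_ids <- case_ids[order(pair_of[case_ids])]
    ctrl_ids <- ctrl_ids[order(pair_of[ctrl_ids])]
    d <- m[, case_ids, drop = FALSE] - m[, ctrl_ids, drop = FALSE]
    n <- length(case_ids)
    logfc <- rowMeans(d)
    s_sq <- apply(d, 1L, var)
    df <- n - 1L
    stdev_unscaled <- 1 / sqrt(n)
  } else {
    mc <- m[, case_ids, drop = FALSE]
    mk <- m[, ctrl_ids, drop = FALSE]
    n1 <- length(case_ids); n2 <- length(ctrl_ids)
    logfc <- rowMeans(mc) - rowMeans(mk)
    s_sq <- ((n1 - 1) * apply(mc, 1L, var) +
               (n2 - 1) * apply(mk, 1L, var)) / (n1 + n2 - 2)
    df <- n1 + n2 - 2L
    stdev_unscaled <- sqrt(1 / n1 + 1 / n2)
  }

  if (thresholds$moderation == "eBayes") {
    mod <- moderate_variances(s_sq, df)
    use_var <- mod$post_var
    df_total <- df + mod$d0
    d0 <- mod$d0; s0_sq <- mod$s0_sq
  } else {
    use_var <- s_sq
    df_total <- df
    d0 <- 0; s0_sq <- NA_real_
    if (any(s_sq == 0)) {
      warnf("%d gene(s) with zero residual variance under ordinary statistics; their p-values are reported as 0",
            sum(s_sq == 0))
    }
  }

  se <- sqrt(use_var) * stdev_unscaled
  t_stat <- logfc / se
  t_stat[se == 0 & logfc == 0] <- 0
  p <- 2 * pt(-abs(t_stat), df = df_total)
  p[is.infinite(t_stat)] <- 0

  res <- data.frame(gene = rownames(m), logFC = unname(logfc),
                    t_stat = unname(t_stat), p_value = unname(p),
                    stringsAsFactors = FALSE)
  res$is_deg <- abs(res$logFC) > thresholds$lfc & res$p_value <= thresholds$alpha
  res$direction <- ifelse(!res$is_deg, "none",
                          ifelse(res$logFC > 0, "up", "down"))
  res <- res[, c("gene", "logFC", "t_stat", "p_value", "direction", "is_deg")]
  res <- res[order(res$gene), ]
  rownames(res) <- NULL
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  attr(res, "df_residual") <- df
  attr(res, "cohort_id") <- study$cohort_id
  class(res) <- c("DEResultTable", "data.frame")
  res
}

#' Call differentially expressed genes
#'
#' Applies the strict fold-change rule `|logFC| > lfc` together with
#' `p <= alpha` and returns the passing genes partitioned into up- and
#' down-regulated, ordered by `|logFC|` descending with ties broken by gene
#' symbol.
#'
#' @param results A `DEResultTable` from [fit_differential()].
#' @param thresholds A [de_thresholds()] object.
#' @return `data.frame` with columns `gene`, `logFC`, `p_value`, `direction`.
#' @export
call_degs <- function(results, thresholds = de_thresholds()) {
  keep <- abs(results$logFC) > thresholds$lfc &
    results$p_value <= thresholds$alpha
  out <- results[keep, c("gene", "logFC", "p_value"), drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  out <- out[order(-abs(out$logFC), out$gene), ]
  rownames(out) <- NULL
  out
}

#' Volcano-plot export table
#'
#' Pure reformat of a result table into the columns a volcano renderer
#' needs: gene, logFC, `-log10(p)` and the DEG flag.
#'
#' @param results A `DEResultTable`.
#' @return `data.frame` with columns `gene`, `logFC`, `neg_log10_p`,
#'   `is_deg`.
#' @export
volcano_table <- function(results) {
  data.frame(gene = results$gene, logFC = results$logFC,
             neg_log10_p = -log10(results$p_value),
             is_deg = results$is_deg, stringsAsFactors = FALSE)
}
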