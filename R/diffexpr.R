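#' Per-gene log2 fold changes between two sample groups
#'
#' Difference of group means on the log2 scale, `group_b` minus `group_a`.
#'
#' @param expr Expression tibble (`gene_id` + sample columns, log2 values).
#' @param classes Named character vector of class labels per sample, or an
#'   annotation data frame with `sample_id` and `class` columns.
#' @param group_a,group_b Class labels to contrast (fold change is
#'   `mean(group_b) - mean(group_a)`).
#' @return A tibble with `gene_id` and `log2fc`.
#' @export
log2_fold_changes <- function(expr, classes, group_a, group_b) {
  m <- expr_to_matrix(expr)
  cl <- resolve_classes(expr, classes)
  for (g in c(group_a, group_b)) {
    if (!any(cl == g)) abort(paste0("unknown or empty class label: ", g))
  }
  lfc <- rowMeans(m[, cl == group_b, drop = FALSE]) -
    rowMeans(m[, cl == group_a, drop = FALSE])
  tibble::tibble(gene_id = rownames(m), log2fc = unname(lfc))
}

#' Moderated two-sample t-statistics with empirical-Bayes variance shrinkage
#'
#' For each gene the pooled within-group variance \eqn{s_g^2} (on
#' \eqn{d_g = n_a + n_b - 2} degrees of freedom) is shrunk toward a prior
#' variance \eqn{s_0^2} carrying \eqn{d_0} prior degrees of freedom:
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' The statistic is `log2fc / (s_tilde * sqrt(1/n_a + 1/n_b))` with a
#' two-sided p-value from the t distribution on \eqn{d_0 + d_g} degrees of
#' freedom. With `prior_df = 0` this is the ordinary pooled two-sample t;
#' as `prior_df` grows the denominator variance approaches `prior_var` for
#' every gene. When both prior parameters are `"auto"` they are estimated
#' by method of moments on the log sample variances.
#'
#' A gene whose shrunken variance is zero (e.g. a constant gene with
#' `prior_df = 0`) is reported with `stat = 0` and `p = 1` rather than
#' dividing by zero.
#'
#' @inheritParams log2_fold_changes
#' @param prior_df Prior degrees of freedom \eqn{d_0}, or `"auto"`.
#' @param prior_var Prior variance \eqn{s_0^2}, or `"auto"`.
#' @return A tibble with `gene_id`, `log2fc`, `stat`, `p`, `heterogeneity`
#'   (pooled within-group sd), `s2` (pooled variance), `df_total`, plus the
#'   resolved `prior_df` / `prior_var` as attributes.
#' @export
moderated_t <- function(expr, classes, group_a, group_b,
                        prior_df = "auto", prior_var = "auto") {
  m <- expr_to_matrix(expr)
  cl <- resolve_classes(expr, classes)
  a <- which(cl == group_a)
  b <- which(cl == group_b)
  if (length(a) == 0 || length(b) == 0) abort("unknown or empty class label")
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 samples for a variance estimate")
  }
  n_a <- length(a); n_b <- length(b)
  d_g <- n_a + n_b - 2

  lfc <- rowMeans(m[, b, drop = FALSE]) - rowMeans(m[, a, drop = FALSE])
  ss_a <- apply(m[, a, drop = FALSE], 1, var) * (n_a - 1)
  ss_b <- apply(m[, b, drop = FALSE], 1, var) * (n_b - 1)
  s2 <- (ss_a + ss_b) / d_g

  auto <- identical(prior_df, "auto") || identical(prior_var, "auto")
  if (auto) {
    mom <- estimate_variance_prior(s2, d_g)
    if (identical(prior_df, "auto")) prior_df <- mom$df
    if (identical(prior_var, "auto")) prior_var <- mom$var
  }
  if (prior_df < 0) abort("prior_df must be nonnegative")
  if (prior_var <= 0) abort("prior_var must be positive")

  if (is.infinite(prior_df)) {
    s2_tilde <- rep(prior_var, length(s2))
    df_total <- Inf
  } else {
    s2_tilde <- (prior_df * prior_var + d_g * s2) / (prior_df + d_g)
    df_total <- prior_df + d_g
  }
  se <- sqrt(s2_tilde * (1 / n_a + 1 / n_b))
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * pt(-abs(stat), df = df_total), 1)

  out <- tibble::tibble(
    gene_id = rownames(m),
    log2fc = unname(lfc),
    stat = unname(stat),
    p = unname(p),
    heterogeneity = unname(sqrt(s2)),
    s2 = unname(s2),
    df_total = df_total
  )
  attr(out, "prior_df") <- prior_df
  attr(out, "prior_var") <- prior_var
  out
}

# Method-of-moments fit of a scaled inverse chi-square prior to observed
# log sample variances (zero variances excluded from the fit).
estimate_variance_prior <- function(s2, d_g) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(df = 0, var = max(mean(s2), .Machine$double.eps)))
  z <- log(s2[ok])
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  e_bar <- mean(e)
  n <- length(e)
  t2 <- mean((e - e_bar)^2) * n / (n - 1) - trigamma(d_g / 2)
  if (is.finite(t2) && t2 > 0) {
    d0 <- 2 * trigamma_inverse(t2)
    s0 <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(e_bar)
  }
  list(df = d0, var = s0)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Select differentially expressed genes
#'
#' Three-stage selection mirroring a standard expression screen: an absolute
#' fold-change threshold (`fold change of 2` meaning `|log2fc| >= 1`),
#' Benjamini-Hochberg adjusted p-value at most `alpha`, then a heterogeneity
#' filter that keeps the `heterogeneity_quantile` fraction of passing genes
#' with the lowest pooled within-group standard deviation (genes that are
#' too heterogeneous across replicates are eliminated). The heterogeneity
#' stage keeps exactly `ceiling(q * k)` of the `k` fc/p-passing genes, ties
#' broken by input gene order.
#'
#' @param de Result tibble from [moderated_t()].
#' @param fc_threshold Linear-scale fold-change threshold (>= 1); a gene
#'   passes when `|log2fc| >= log2(fc_threshold)`.
#' @param alpha Benjamini-Hochberg adjusted p-value cutoff.
#' @param heterogeneity_quantile Fraction (0, 1\] of fc/p-passing genes
#'   retained by the heterogeneity filter; 1 disables it.
#' @return The input tibble with `p_adj`, `selected` and `direction`
#'   columns added; up/down counts of selected genes as attributes
#'   `n_up` / `n_down`.
#' @export
select_de <- function(de, fc_threshold = 2, alpha = 0.05,
                      heterogeneity_quantile = 0.47) {
  if (fc_threshold < 1) abort("fc_threshold must be >= 1")
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")
  if (heterogeneity_quantile <= 0 || heterogeneity_quantile > 1) {
    abort("heterogeneity_quantile must lie in (0, 1]")
  }
  de <- dplyr::mutate(de,
    p_adj = p.adjust(.data$p, method = "BH"),
    direction = ifelse(.data$log2fc > 0, "up", "down")
  )
  pass <- which(abs(de$log2fc) >= log2(fc_threshold) & de$p_adj <= alpha)
  if (length(pass) == 0) {
    warn("no gene passes the fold-change/p-value stage; empty selection")
    de$selected <- FALSE
  } else {
    n_keep <- ceiling(heterogeneity_quantile * length(pass))
    keep <- pass[order(de$heterogeneity[pass], pass)][seq_len(n_keep)]
    de$selected <- seq_len(nrow(de)) %in% keep
  }
  attr(de, "n_up") <- sum(de$selected & de$direction == "up")
  attr(de, "n_down") <- sum(de$selected & de$direction == "down")
  de
}

#' Full differential-expression stage
#'
#' Convenience wrapper chaining [moderated_t()] and [select_de()].
#'
#' @inheritParams moderated_t
#' @inheritParams select_de
#' @return A selection-flagged tibble as from [select_de()].
#' @export
differential_expression <- function(expr, classes, group_a, group_b,
                                    fc_threshold = 2, alpha = 0.05,
                                    heterogeneity_quantile = 0.47,
                                    prior_df = "auto", prior_var = "auto") {
  de <- moderated_t(expr, classes, group_a, group_b, prior_df, prior_var)
  select_de(de, fc_threshold, alpha, heterogeneity_quantile)
}
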