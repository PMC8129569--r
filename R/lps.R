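#' Fit a linear-predictor-score (LPS) Bayesian classifier
#'
#' Each gene receives a coefficient equal to its ordinary two-sample
#' t-statistic between the positive and negative class on the training
#' data (positive minus negative, pooled variance). A sample's LPS is the
#' weighted sum of its expression values, `sum_j a_j x_j`; one Gaussian is
#' fitted to the training LPS scores of each class. The posterior
#' probability of positive-class membership for a new sample follows from
#' the two normal densities, and the three-way call (positive / negative /
#' not attributed) uses the `p_hi` / `p_lo` thresholds.
#'
#' @param expr Training expression tibble (`gene_id` + sample columns).
#' @param classes Class labels (named vector or annotation data frame).
#' @param positive_class Label of the positive (signature-carrying) class;
#'   every other label is treated as negative.
#' @param genes Genes to use; defaults to all rows.
#' @param p_hi Posterior threshold for a positive call (default 0.9).
#' @param p_lo Posterior threshold for a negative call (default 0.1).
#' @return An object of class `lps_model`.
#' @export
fit_lps <- function(expr, classes, positive_class, genes = NULL,
                    p_hi = 0.9, p_lo = 0.1) {
  if (p_lo < 0 || p_hi > 1 || p_lo >= p_hi) {
    abort("need 0 <= p_lo < p_hi <= 1")
  }
  m <- expr_to_matrix(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) {
      abort(paste0("genes absent from the matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  cl <- resolve_classes(expr, classes)
  pos <- cl == positive_class
  if (all(pos) || all(!pos)) abort("training data contains a single class")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2 || n0 < 2) abort("each class needs at least 2 training samples")

  mu1 <- rowMeans(m[, pos, drop = FALSE])
  mu0 <- rowMeans(m[, !pos, drop = FALSE])
  ss1 <- apply(m[, pos, drop = FALSE], 1, var) * (n1 - 1)
  ss0 <- apply(m[, !pos, drop = FALSE], 1, var) * (n0 - 1)
  s2 <- (ss1 + ss0) / (n1 + n0 - 2)
  se <- sqrt(s2 * (1 / n1 + 1 / n0))
  a <- ifelse(se > 0, (mu1 - mu0) / se, 0)
  if (any(se == 0)) {
    warn("gene(s) with zero pooled variance receive coefficient 0")
  }

  scores <- drop(crossprod(m, a))
  s1 <- sd(scores[pos]); s0 <- sd(scores[!pos])
  if (s1 == 0 || s0 == 0) abort("degenerate training LPS scores (zero class sd)")
  structure(
    list(
      genes = rownames(m),
      coefficients = setNames(unname(a), rownames(m)),
      class1_mean = mean(scores[pos]), class1_sd = s1,
      class0_mean = mean(scores[!pos]), class0_sd = s0,
      p_hi = p_hi, p_lo = p_lo,
      positive_class = positive_class
    ),
    class = "lps_model"
  )
}

#' Linear predictor scores for samples
#'
#' `sum_j a_j x_j` over the model's genes, in model gene order. Missing
#' gene values are an error — there is no silent imputation.
#'
#' @param model An `lps_model`.
#' @param expr Expression tibble covering the model genes, or a named
#'   numeric vector for a single sample profile.
#' @return A tibble with `sample_id` and `lps`, or a single number for a
#'   vector profile.
#' @export
lps_score <- function(model, expr) {
  if (is.numeric(expr)) {
    missing <- setdiff(model$genes, names(expr))
    if (length(missing) > 0) abort("profile is missing model gene value(s)")
    return(sum(model$coefficients * expr[model$genes]))
  }
  m <- expr_to_matrix(expr)
  missing <- setdiff(model$genes, rownames(m))
  if (length(missing) > 0) abort("matrix is missing model gene(s)")
  scores <- drop(crossprod(m[model$genes, , drop = FALSE], model$coefficients))
  tibble::tibble(sample_id = colnames(m), lps = unname(scores))
}

#' Posterior probability of positive-class membership
#'
#' `phi(s; mu1, sd1) / (phi(s; mu1, sd1) + phi(s; mu0, sd0))` with `phi`
#' the normal density, evaluated on the log scale for numerical stability.
#'
#' @param model An `lps_model`.
#' @param score Numeric LPS score(s).
#' @return Posterior probabilities in \[0, 1\].
#' @export
posterior_wm <- function(model, score) {
  l1 <- dnorm(score, model$class1_mean, model$class1_sd, log = TRUE)
  l0 <- dnorm(score, model$class0_mean, model$class0_sd, log = TRUE)
  1 / (1 + exp(l0 - l1))
}

#' Three-way classification from the posterior
#'
#' Positive when the posterior reaches `p_hi`, negative when it is at most
#' `p_lo`, and `"NA"` (not attributed) in between.
#'
#' @param model An `lps_model`.
#' @param posterior Posterior probabilities.
#' @return Character vector of calls: the positive class label, `"nonWM"`
#'   (literally `non<positive_class>`), or `"NA"`.
#' @export
classify_lps <- function(model, posterior) {
  neg <- paste0("non", model$positive_class)
  dplyr::case_when(
    posterior >= model$p_hi ~ model$positive_class,
    posterior <= model$p_lo ~ neg,
    .default = "NA"
  )
}

#' Predict class membership for new samples
#'
#' @param object An `lps_model`.
#' @param expr Expression tibble covering the model genes.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `lps`, `posterior`, `call`.
#' @export
predict.lps_model <- function(object, expr, ...) {
  scores <- lps_score(object, expr)
  scores$posterior <- posterior_wm(object, scores$lps)
  scores$call <- classify_lps(object, scores$posterior)
  scores
}

#' Refine a candidate gene set into a compact predictor
#'
#' Candidates are ranked by the absolute value of their training
#' t-statistic coefficient; gene prefixes of increasing size are scored by
#' leave-one-out assignment quality (+1 for a correct call, 0 for a
#' not-attributed call, -1 for a wrong call, summed over training samples)
#' and the best-scoring prefix is returned (ties resolved toward fewer
#' genes), capped at `max_genes`.
#'
#' @inheritParams fit_lps
#' @param candidate_genes Candidate gene ids (non-empty, all in `expr`).
#' @param max_genes Cap on the predictor size (default no cap).
#' @return A list with `genes` (chosen subset), `model` (refit on all
#'   training data), `n_up` / `n_down` (coefficient sign split), and
#'   `loo` (tibble of prefix sizes and leave-one-out scores).
#' @export
refine_predictor <- function(expr, classes, positive_class, candidate_genes,
                             max_genes = Inf, p_hi = 0.9, p_lo = 0.1) {
  if (length(candidate_genes) == 0) abort("empty candidate gene list")
  full <- fit_lps(expr, classes, positive_class, genes = candidate_genes,
                  p_hi = p_hi, p_lo = p_lo)
  ranked <- names(sort(abs(full$coefficients), decreasing = TRUE))
  n_prefix <- min(length(ranked), max_genes)
  cl <- resolve_classes(expr, classes)
  samples <- setdiff(names(expr), "gene_id")

  loo_score <- function(genes) {
    score <- 0L
    for (s in samples) {
      train <- expr[, c("gene_id", setdiff(samples, s))]
      fit <- try(fit_lps(train, cl[setdiff(samples, s)], positive_class,
                         genes = genes, p_hi = p_hi, p_lo = p_lo),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      pred <- suppressWarnings(predict(fit, expr[, c("gene_id", s)]))
      truth <- if (cl[s] == positive_class) positive_class else
        paste0("non", positive_class)
      score <- score + ifelse(pred$call == truth, 1L,
                              ifelse(pred$call == "NA", 0L, -1L))
    }
    score
  }

  scores <- vapply(seq_len(n_prefix), function(i) loo_score(ranked[seq_len(i)]),
                   integer(1))
  best <- which.max(scores) # first max = fewest genes
  genes <- ranked[seq_len(best)]
  model <- fit_lps(expr, classes, positive_class, genes = genes,
                   p_hi = p_hi, p_lo = p_lo)
  list(
    genes = genes,
    model = model,
    n_up = sum(model$coefficients > 0),
    n_down = sum(model$coefficients < 0),
    loo = tibble::tibble(n_genes = seq_len(n_prefix), loo_score = scores)
  )
}

#' Serialize and restore an LPS model as JSON
#'
#' @param model An `lps_model`.
#' @param path JSON file path.
#' @return The path (writer, invisibly) or the restored model (reader).
#' @export
write_lps_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_lps_model
#' @export
read_lps_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$coefficients <- setNames(as.numeric(raw$coefficients), raw$genes)
  structure(raw, class = "lps_model")
}

#' @export
print.lps_model <- function(x, ...) {
  cat("Linear predictor score model:", length(x$genes), "genes\n")
  cat(sprintf("  %s scores ~ N(%.3f, %.3f); other ~ N(%.3f, %.3f)\n",
              x$positive_class, x$class1_mean, x$class1_sd,
              x$class0_mean, x$class0_sd))
  cat(sprintf("  call thresholds: >= %.2f -> %s, <= %.2f -> non%s\n",
              x$p_hi, x$positive_class, x$p_lo, x$positive_class))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.lps_model <- function(x, ...) {
  tibble::tibble(
    gene = x$genes,
    coefficient = unname(x$coefficients),
    direction = ifelse(unname(x$coefficients) > 0, "up", "down")
  )
}

#' @rdname tidy
#' @export
glance.lps_model <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    class1_mean = x$class1_mean, class1_sd = x$class1_sd,
    class0_mean = x$class0_mean, class0_sd = x$class0_sd,
    p_hi = x$p_hi, p_lo = x$p_lo
  )
}
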