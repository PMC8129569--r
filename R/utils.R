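#' @importFrom rlang abort warn .data
#' @importFrom stats sd var dnorm pt qnorm p.adjust kmeans hclust cutree dist
#'   prcomp rnorm rbinom setNames
#' @importFrom utils head adist combn
NULL

# Convert an expression tibble (gene_id + one column per sample) to a
# numeric matrix with gene_id rownames. Validates uniqueness and missingness.
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr))
  if (!"gene_id" %in% names(expr)) {
    abort("expression table must have a `gene_id` first column")
  }
  genes <- as.character(expr$gene_id)
  if (anyDuplicated(genes)) abort("duplicate gene_id values in expression table")
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids in expression table")
  if (!is.numeric(m)) abort("expression values must be numeric")
  if (anyNA(m)) abort("expression table contains missing values; impute or filter first")
  rownames(m) <- genes
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "gene_id")
}

# Resolve a class-label vector for the samples of an expression tibble from
# either a named character vector or an annotation data frame with
# sample_id / class columns.
resolve_classes <- function(expr, classes) {
  samples <- setdiff(names(expr), "gene_id")
  if (is.data.frame(classes)) {
    if (!all(c("sample_id", "class") %in% names(classes))) {
      abort("annotation table needs `sample_id` and `class` columns")
    }
    cl <- setNames(as.character(classes$class), as.character(classes$sample_id))
  } else {
    cl <- classes
  }
  missing <- setdiff(samples, names(cl))
  if (length(missing) > 0) {
    abort(paste0("no class label for sample(s): ", paste(missing, collapse = ", ")))
  }
  cl[samples]
}

# Standardize gene rows to mean 0 / sd 1 across samples; constant rows -> 0.
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  s[s == 0] <- 1
  (m - mu) / s
}

`%||%` <- function(x, y) if (is.null(x)) y else x
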