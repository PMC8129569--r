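#' Initial k-means partition of gene expression profiles
#'
#' Genes (rows) are standardized to mean 0 / sd 1 across samples and
#' partitioned by k-means with the squared-Euclidean objective, keeping the
#' best of `restarts` runs by within-cluster inertia. Empty clusters are
#' dropped and indices re-compacted, so the result always has contiguous
#' cluster labels `1..k`.
#'
#' @param expr Expression tibble (`gene_id` + sample columns), typically
#'   restricted to the selected differentially expressed genes.
#' @param k_init Number of initial clusters (default 40).
#' @param seed Integer seed controlling the k-means starts.
#' @param restarts Number of random restarts (default 10).
#' @param genes Optional character vector restricting the rows used.
#' @return An object of class `agg_state`: a list with `assignment` (named
#'   integer vector gene -> cluster), `centroids` (k x samples matrix of
#'   cluster mean profiles), `data` (the standardized gene matrix),
#'   `k_init`, `trace` (empty until [aggregate_clusters()]), `k_star`.
#' @export
initial_kmeans <- function(expr, k_init = 40, seed = 1, restarts = 10,
                           genes = NULL) {
  m <- expr_to_matrix(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) abort("genes not present in the matrix")
    m <- m[genes, , drop = FALSE]
  }
  if (nrow(m) < k_init) {
    abort(paste0("fewer genes (", nrow(m), ") than k_init (", k_init,
                 "); use a smaller k_init"))
  }
  x <- standardize_rows(m)
  km <- withr::with_seed(seed, {
    kmeans(x, centers = k_init, nstart = restarts, iter.max = 100)
  })
  assignment <- km$cluster
  # drop empty clusters, re-compact to 1..k
  used <- sort(unique(assignment))
  assignment <- match(assignment, used)
  names(assignment) <- rownames(x)
  new_agg_state(assignment, x, k_init)
}

new_agg_state <- function(assignment, x, k_init) {
  structure(
    list(
      assignment = assignment,
      centroids = compute_centroids(assignment, x),
      data = x,
      k_init = k_init,
      trace = tibble::tibble(step = integer(), pair_a = integer(),
                             pair_b = integer(), k = integer(),
                             chi2 = numeric(), std_chi2 = numeric()),
      k_star = NULL,
      snapshots = list()
    ),
    class = "agg_state"
  )
}

compute_centroids <- function(assignment, x) {
  k <- max(assignment)
  cent <- matrix(NA_real_, nrow = k, ncol = ncol(x),
                 dimnames = list(seq_len(k), colnames(x)))
  for (c_i in seq_len(k)) {
    cent[c_i, ] <- colMeans(x[assignment == c_i, , drop = FALSE])
  }
  cent
}

#' Pairwise centroid distances in principal-component space
#'
#' Cluster centroids are column-centered and projected onto the first
#' `min(2, k - 1)` principal components of the centroid matrix; the output
#' is the Euclidean distance between projections. The projection is
#' recomputed fresh from the current centroids at every call.
#'
#' @param state An `agg_state`.
#' @return A symmetric k x k distance matrix.
#' @export
centroid_pc_distance <- function(state) {
  cent <- state$centroids
  k <- nrow(cent)
  if (k < 2) abort("at least 2 clusters are required for a distance table")
  pcs <- min(2, k - 1)
  proj <- prcomp(cent, center = TRUE, scale. = FALSE)$x[, seq_len(pcs), drop = FALSE]
  as.matrix(dist(proj))
}

#' Standardized chi-square concordance between two partitions
#'
#' Pearson chi-square on the contingency table of `assignment` against
#' `reference` labels (empty rows/columns removed), with
#' `df = (r - 1)(c - 1)` and the standardization
#' `std_chi2 = (chi2 - df) / sqrt(2 df)` that makes values comparable
#' across table sizes. A degenerate table (`df = 0`) yields both values 0.
#'
#' @param assignment,reference Vectors of labels over the same genes; when
#'   both are named the reference is aligned by name.
#' @return A list with `chi2`, `df`, `std_chi2`.
#' @export
chi2_criterion <- function(assignment, reference) {
  if (!is.null(names(assignment)) && !is.null(names(reference))) {
    if (!setequal(names(assignment), names(reference))) {
      abort("assignment and reference cover different gene sets")
    }
    reference <- reference[names(assignment)]
  } else if (length(assignment) != length(reference)) {
    abort("assignment and reference cover different gene sets")
  }
  tab <- table(assignment, reference)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  r <- nrow(tab); c_ <- ncol(tab)
  df <- (r - 1) * (c_ - 1)
  if (df == 0) return(list(chi2 = 0, df = 0, std_chi2 = 0))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  list(chi2 = chi2, df = df, std_chi2 = (chi2 - df) / sqrt(2 * df))
}

#' Greedy pairwise agglomeration with a chi-square stopping rule
#'
#' Starting from the k-means partition, the two clusters closest in
#' principal-component space are merged (ties broken by the
#' lexicographically smallest index pair), centroids are recomputed, and the
#' standardized chi-square of the current partition against a reference
#' partition is recorded; this repeats until two clusters remain. The
#' returned state is restored at `k_star`, the cluster count maximizing
#' `|std_chi2|` over the merge trace (ties resolved toward the largest k).
#'
#' Two reference modes are available. `"hierarchical"` (default) uses a
#' Ward-linkage hierarchical clustering of the same standardized gene
#' profiles cut at the current k, so the criterion measures concordance
#' between the k-means agglomeration and an independent hierarchical view
#' of the same genes. `"direction"` cross-tabulates cluster membership
#' against each gene's up/down fold-change direction.
#'
#' @param state An `agg_state` from [initial_kmeans()].
#' @param reference_mode `"hierarchical"` or `"direction"`.
#' @param de Differential result tibble with `gene_id` and `direction`
#'   (required for `reference_mode = "direction"`).
#' @return The `agg_state` with `trace` filled, `k_star` set, and
#'   `assignment`/`centroids` restored at `k_star`.
#' @export
aggregate_clusters <- function(state, reference_mode = c("hierarchical", "direction"),
                               de = NULL) {
  reference_mode <- match.arg(reference_mode)
  if (state$k_init < 3 || max(state$assignment) < 3) {
    state$k_star <- max(state$assignment)
    return(state)
  }
  x <- state$data
  ref_fun <- switch(reference_mode,
    hierarchical = {
      hc <- hclust(dist(x), method = "ward.D2")
      function(k) cutree(hc, k = k)
    },
    direction = {
      if (is.null(de)) abort("reference_mode = 'direction' requires a `de` table")
      dir <- setNames(de$direction, de$gene_id)[rownames(x)]
      if (anyNA(dir)) abort("`de` table does not cover all clustered genes")
      function(k) dir
    }
  )

  assignment <- state$assignment
  trace <- list()
  snapshots <- list()
  step <- 0L
  k <- max(assignment)
  while (k > 2) {
    tmp_state <- state
    tmp_state$assignment <- assignment
    tmp_state$centroids <- compute_centroids(assignment, x)
    d <- centroid_pc_distance(tmp_state)
    pair <- closest_pair(d)
    assignment <- merge_pair(assignment, pair[1], pair[2])
    k <- k - 1L
    step <- step + 1L
    crit <- chi2_criterion(assignment, ref_fun(k))
    trace[[step]] <- tibble::tibble(step = step, pair_a = pair[1],
                                    pair_b = pair[2], k = k,
                                    chi2 = crit$chi2, std_chi2 = crit$std_chi2)
    snapshots[[as.character(k)]] <- assignment
  }
  state$trace <- purrr::list_rbind(trace)
  best <- which.max(abs(state$trace$std_chi2)) # trace is in decreasing k: first max = largest k
  state$k_star <- state$trace$k[best]
  state$assignment <- snapshots[[as.character(state$k_star)]]
  state$centroids <- compute_centroids(state$assignment, x)
  state$snapshots <- snapshots
  state
}

# smallest (i, j) pair attaining the minimum off-diagonal distance
closest_pair <- function(d) {
  k <- nrow(d)
  best <- c(NA_integer_, NA_integer_)
  best_d <- Inf
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (d[i, j] < best_d - 1e-12) {
        best_d <- d[i, j]
        best <- c(i, j)
      }
    }
  }
  best
}

# merge cluster j into i and re-compact labels to 1..k-1
merge_pair <- function(assignment, i, j) {
  assignment[assignment == j] <- i
  used <- sort(unique(assignment))
  out <- match(assignment, used)
  names(out) <- names(assignment)
  out
}

#' @export
print.agg_state <- function(x, ...) {
  cat("Gene-cluster aggregation state\n")
  cat("  genes:", length(x$assignment), " k_init:", x$k_init, "\n")
  cat("  current k:", max(x$assignment), "\n")
  if (!is.null(x$k_star)) cat("  k_star:", x$k_star, "\n")
  invisible(x)
}

#' Tidy a gene-cluster aggregation state
#'
#' @param x An `agg_state`.
#' @param ... Unused.
#' @return A tibble with `gene_id` and `cluster`.
#' @export
tidy.agg_state <- function(x, ...) {
  tibble::tibble(gene_id = names(x$assignment), cluster = unname(x$assignment))
}

#' One-row summary of an aggregation state
#'
#' @param x An `agg_state`.
#' @param ... Unused.
#' @return A one-row tibble with `n_genes`, `k_init`, `k_star`,
#'   `max_abs_std_chi2`.
#' @export
glance.agg_state <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$assignment),
    k_init = x$k_init,
    k_star = x$k_star %||% NA_integer_,
    max_abs_std_chi2 = if (nrow(x$trace) > 0) max(abs(x$trace$std_chi2)) else NA_real_
  )
}

#' Generic tidy/glance verbs
#'
#' Broom-style verbs for the package's fitted objects.
#' @param x An object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
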