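# Small fixtures built in code for the unit tests.

# tiny expression tibble from a plain matrix
toy_expr <- function(m, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  tibble::as_tibble(as.data.frame(m), rownames = "gene_id")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# two-class cohort with the standard study shape (3 + 4 samples)
small_cohort <- function(seed = 1, n_genes = 200, effect = 3, noise_sd = 0.3,
                         n_planted = 20) {
  simulate_expression_cohort(
    n_genes = n_genes,
    cluster_spec = data.frame(size = n_planted, effect = effect,
                              direction = "up"),
    classes = data.frame(label = c("WT", "MUT"), n = c(3, 4)),
    noise_sd = noise_sd, seed = seed
  )
}

# brute-force rank-sum p-value by direct enumeration over group assignments
ranksum_bruteforce <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  sums <- apply(combn(n + m, n), 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= w_obs + eps), mean(sums >= w_obs - eps)))
}

# agg_state over raw (unstandardized) profiles with a fixed assignment —
# lets tests place centroids at exact coordinates
new_state_for_test <- function(expr, assignment) {
  x <- sigclone:::expr_to_matrix(expr)
  st <- sigclone:::new_agg_state(assignment, x, k_init = max(assignment))
  st
}

as_signature_for_test <- function(tbl) sigclone:::as_signature(tbl)

# exhaustive agglomeration oracle: explore every closest-pair merge
# sequence (all tie choices) and return the best |std_chi2| attained and
# the set of (k, partition) optima, mirroring the greedy loop independently
exhaustive_agglomeration <- function(x, assignment, ref_fun) {
  best <- new.env(parent = emptyenv())
  best$val <- -Inf; best$ks <- integer()
  recurse <- function(assignment) {
    k <- max(assignment)
    if (k <= 2) return()
    cent <- t(vapply(seq_len(k), function(c_i) {
      colMeans(x[assignment == c_i, , drop = FALSE])
    }, numeric(ncol(x))))
    proj <- prcomp(cent, center = TRUE)$x[, seq_len(min(2, k - 1)), drop = FALSE]
    d <- as.matrix(dist(proj))
    diag(d) <- Inf
    dmin <- min(d)
    pairs <- which(d <= dmin + 1e-12 & upper.tri(d), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      a2 <- assignment
      a2[a2 == pairs[r, 2]] <- pairs[r, 1]
      a2 <- setNames(match(a2, sort(unique(a2))), names(assignment))
      crit <- chi2_criterion(a2, ref_fun(k - 1))
      v <- abs(crit$std_chi2)
      if (v > best$val + 1e-12) {
        best$val <- v; best$ks <- k - 1
      } else if (abs(v - best$val) <= 1e-12) {
        best$ks <- union(best$ks, k - 1)
      }
      recurse(a2)
    }
  }
  recurse(assignment)
  list(val = best$val, ks = best$ks)
}

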