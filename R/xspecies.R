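#' Collapse probesets to genes
#'
#' When several probesets map onto one gene, the probeset with the highest
#' mean expression across samples is kept (a common summarization
#' convention for array data). Unmapped probesets are dropped with a logged
#' count.
#'
#' @param expr Expression tibble keyed by probeset id in `gene_id`.
#' @param probe_map Data frame with columns `probeset` and `gene`; every
#'   probeset maps to at most one gene.
#' @return An expression tibble keyed by gene.
#' @export
collapse_probesets <- function(expr, probe_map) {
  probe_map <- tibble::as_tibble(probe_map)
  if (nrow(probe_map) == 0) abort("empty probeset-to-gene mapping")
  if (!all(c("probeset", "gene") %in% names(probe_map))) {
    abort("probe_map needs `probeset` and `gene` columns")
  }
  if (anyDuplicated(probe_map$probeset)) {
    abort("a probeset maps to more than one gene")
  }
  m <- expr_to_matrix(expr)
  mapped <- intersect(rownames(m), probe_map$probeset)
  dropped <- nrow(m) - length(mapped)
  if (dropped > 0) {
    rlang::inform(paste0("collapse_probesets: dropped ", dropped,
                         " unmapped probeset(s)"))
  }
  if (length(mapped) == 0) abort("no probeset of the matrix is covered by the mapping")
  gene_of <- setNames(probe_map$gene, probe_map$probeset)[mapped]
  means <- rowMeans(m[mapped, , drop = FALSE])
  pick <- tibble::tibble(probeset = mapped, gene = unname(gene_of),
                         mean_expr = unname(means)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$mean_expr, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- m[pick$probeset, , drop = FALSE]
  rownames(out) <- pick$gene
  matrix_to_expr(out)
}

#' Map mouse genes to human orthologs
#'
#' With an explicit two-column mapping the table is used verbatim;
#' otherwise genes are paired by case-insensitive symbol equality (the
#' mouse title-case / human upper-case convention, e.g. `Irf4` / `IRF4`).
#' Output pairs are unique per mouse gene.
#'
#' @param mouse_genes,human_genes Character vectors of gene symbols.
#' @param explicit_map Optional data frame with `mouse_gene`, `human_gene`.
#' @return A tibble with `mouse_gene` and `human_gene`.
#' @export
map_orthologs <- function(mouse_genes, human_genes, explicit_map = NULL) {
  if (!is.null(explicit_map)) {
    explicit_map <- tibble::as_tibble(explicit_map)
    if (anyDuplicated(explicit_map$mouse_gene)) {
      abort("duplicate mouse gene in explicit ortholog map")
    }
    return(explicit_map[, c("mouse_gene", "human_gene")])
  }
  idx <- match(toupper(mouse_genes), toupper(human_genes))
  keep <- !is.na(idx) & !duplicated(mouse_genes)
  tibble::tibble(
    mouse_gene = mouse_genes[keep],
    human_gene = human_genes[idx[keep]]
  )
}

#' Extract the cross-species sign-coherent signature
#'
#' Keeps ortholog pairs where both species pass their differential
#' selection and the fold changes agree in sign; the shared direction is
#' recorded per entry and up/down counts are tallied. This is the
#' cross-species signature concept: genes coherently dysregulated in both
#' the mouse tumors and the human WM cohort.
#'
#' @param mouse_de,human_de Selection-flagged tibbles from [select_de()]
#'   (columns `gene_id`, `log2fc`, `selected`).
#' @param pairs Ortholog pairs from [map_orthologs()].
#' @return A tibble of class `signature` with `mouse_gene`, `human_gene`,
#'   `direction`; attributes `n_up` and `n_down`.
#' @export
coherent_signature <- function(mouse_de, human_de, pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) {
    warn("empty ortholog pair list; empty signature")
    out <- tibble::tibble(mouse_gene = character(), human_gene = character(),
                          direction = character())
    return(as_signature(out))
  }
  mi <- match(pairs$mouse_gene, mouse_de$gene_id)
  hi <- match(pairs$human_gene, human_de$gene_id)
  ok <- !is.na(mi) & !is.na(hi)
  mi <- mi[ok]; hi <- hi[ok]; pairs <- pairs[ok, ]
  m_lfc <- mouse_de$log2fc[mi]
  h_lfc <- human_de$log2fc[hi]
  keep <- mouse_de$selected[mi] & human_de$selected[hi] &
    sign(m_lfc) == sign(h_lfc) & sign(m_lfc) != 0
  out <- tibble::tibble(
    mouse_gene = pairs$mouse_gene[keep],
    human_gene = pairs$human_gene[keep],
    direction = ifelse(m_lfc[keep] > 0, "up", "down")
  )
  if (nrow(out) == 0) warn("no sign-coherent selected pair; empty signature")
  as_signature(out)
}

as_signature <- function(tbl) {
  attr(tbl, "n_up") <- sum(tbl$direction == "up")
  attr(tbl, "n_down") <- sum(tbl$direction == "down")
  class(tbl) <- c("signature", class(tbl))
  tbl
}

#' Branch coherency of a signature between two cohorts
#'
#' In each matrix independently, the signature-gene profiles (standardized
#' per gene) are clustered hierarchically with Ward linkage and cut into
#' two branches; each branch is labeled up or down by the sign of the mean
#' group contrast of its genes. Coherency is the fraction of signature
#' genes that receive the same branch label in both matrices — the
#' quantitative analogue of comparing up/down dendrogram branches across
#' species.
#'
#' @param expr_a,expr_b Expression tibbles containing the signature genes
#'   (mouse symbols for one, human symbols for the other; either column of
#'   the signature may match either matrix).
#' @param signature A `signature` tibble.
#' @param classes_a,classes_b Class labels for each matrix (named vector or
#'   annotation data frame).
#' @param contrast_a,contrast_b Length-2 character vectors
#'   `c(group_a, group_b)` defining each matrix's contrast
#'   (`group_b - group_a`).
#' @return The coherency fraction in \[0, 1\], with the per-gene branch
#'   labels attached as attribute `labels`.
#' @export
branch_coherency <- function(expr_a, expr_b, signature,
                             classes_a, contrast_a,
                             classes_b, contrast_b) {
  if (nrow(signature) < 2) abort("signature must contain at least 2 genes")
  genes_a <- signature_genes_in(expr_a, signature)
  genes_b <- signature_genes_in(expr_b, signature)
  lab_a <- branch_labels(expr_a, genes_a, classes_a, contrast_a)
  lab_b <- branch_labels(expr_b, genes_b, classes_b, contrast_b)
  coherency <- mean(lab_a == lab_b)
  attr(coherency, "labels") <- tibble::tibble(
    mouse_gene = signature$mouse_gene,
    human_gene = signature$human_gene,
    branch_a = lab_a, branch_b = lab_b
  )
  coherency
}

# pick whichever signature column matches the matrix's gene ids
signature_genes_in <- function(expr, signature) {
  ids <- expr$gene_id
  if (all(signature$mouse_gene %in% ids)) return(signature$mouse_gene)
  if (all(signature$human_gene %in% ids)) return(signature$human_gene)
  abort("signature genes not all present in the matrix")
}

branch_labels <- function(expr, genes, classes, contrast) {
  m <- expr_to_matrix(expr)[genes, , drop = FALSE]
  cl <- resolve_classes(expr, classes)
  x <- standardize_rows(m)
  branch <- cutree(hclust(dist(x), method = "ward.D2"), k = 2)
  lfc <- rowMeans(m[, cl == contrast[2], drop = FALSE]) -
    rowMeans(m[, cl == contrast[1], drop = FALSE])
  labels <- character(length(genes))
  for (b in 1:2) {
    in_b <- branch == b
    mb <- mean(lfc[in_b])
    if (mb == 0) {
      # degenerate branch: fall back to the majority of individual signs
      warn("branch with zero mean contrast; labeled by majority gene direction")
      lab <- if (sum(sign(lfc[in_b])) >= 0) "up" else "down"
    } else {
      lab <- if (mb > 0) "up" else "down"
    }
    labels[in_b] <- lab
  }
  setNames(labels, genes)
}

#' Overlap summary of a signature's branch assignment
#'
#' Cross-tabulates the two cohorts' branch labels for the signature genes —
#' the numeric analogue of Venn diagrams of branch intersections.
#'
#' @param coherency A value returned by [branch_coherency()].
#' @return A list with entry counts suitable for JSON serialization.
#' @export
signature_overlap <- function(coherency) {
  labs <- attr(coherency, "labels")
  list(
    n_genes = nrow(labs),
    coherency = as.numeric(coherency),
    up_up = sum(labs$branch_a == "up" & labs$branch_b == "up"),
    down_down = sum(labs$branch_a == "down" & labs$branch_b == "down"),
    up_down = sum(labs$branch_a == "up" & labs$branch_b == "down"),
    down_up = sum(labs$branch_a == "down" & labs$branch_b == "up")
  )
}
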