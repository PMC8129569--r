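#' Default pipeline configuration
#'
#' Defaults follow the analysis the package reimplements: fold-change
#' threshold 2, 40 initial k-means clusters, top-5 clone reporting, LPS
#' call thresholds 0.9/0.1.
#'
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    paths = list(
      mouse_matrix = NULL, mouse_annot = NULL,
      human_matrix = NULL, human_annot = NULL,
      validation_matrix = NULL, validation_annot = NULL,
      airr = NULL, fastq_r1 = NULL, fastq_r2 = NULL,
      barcode_table = NULL, primer_table = NULL,
      rep_groups = NULL, outdir = NULL
    ),
    contrasts = list(
      mouse_control = NULL, mouse_case = NULL, human_positive = NULL
    ),
    diffexpr = list(fc_threshold = 2, alpha = 0.05,
                    heterogeneity_quantile = 0.47,
                    prior_df = "auto", prior_var = "auto"),
    aggclust = list(k_init = 40, restarts = 10,
                    reference_mode = "hierarchical"),
    lps = list(p_hi = 0.9, p_lo = 0.1, max_genes = NULL),
    clonality = list(n_top = 5, min_overlap = 10, max_mismatch_density = 0.25,
                     count_mode = "duplicate_count"),
    seed = 1
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills unset fields from [default_config()], rejects
#' unknown keys (suggesting the closest known key), and range-checks the
#' numeric parameters.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Optional nested list applied on top (useful in code).
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- unclass(default_config())
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  if (!is.null(overrides)) user <- modify_nested(user, overrides)
  check_keys(user, cfg, prefix = NULL)
  cfg <- modify_nested(cfg, user)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

modify_nested <- function(base, new) {
  for (k in names(new)) {
    if (is.list(new[[k]]) && is.list(base[[k]])) {
      base[[k]] <- modify_nested(base[[k]], new[[k]])
    } else {
      base[[k]] <- new[[k]]
    }
  }
  base
}

# common synonyms, mapped to the canonical configuration key
config_aliases <- c(
  fold_change = "fc_threshold", fdr = "alpha", q_value = "alpha",
  k = "k_init", n_clusters = "k_init", nstart = "restarts",
  top_n = "n_top", overlap = "min_overlap"
)

check_keys <- function(user, known, prefix) {
  unknown <- setdiff(names(user), names(known))
  if (length(unknown) > 0) {
    key <- unknown[1]
    candidates <- c(setNames(names(known), names(known)), config_aliases)
    dists <- adist(key, names(candidates), ignore.case = TRUE)
    hint <- unname(candidates[which.min(dists)])
    where <- if (is.null(prefix)) "" else paste0(" in `", prefix, "`")
    abort(paste0("unknown configuration key `", key, "`", where,
                 "; did you mean `", hint, "`?"))
  }
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(known[[k]]) && length(names(known[[k]]))) {
      check_keys(user[[k]], known[[k]], k)
    }
  }
}

validate_config <- function(cfg) {
  in_range <- function(v, lo, hi, name, lo_open = FALSE, hi_open = FALSE) {
    bad <- if (lo_open) v <= lo else v < lo
    bad <- bad || if (hi_open) v >= hi else v > hi
    if (bad) abort(paste0("configuration field `", name, "` out of range"))
  }
  d <- cfg$diffexpr
  in_range(d$fc_threshold, 1, Inf, "diffexpr$fc_threshold")
  in_range(d$alpha, 0, 1, "diffexpr$alpha", lo_open = TRUE)
  in_range(d$heterogeneity_quantile, 0, 1, "diffexpr$heterogeneity_quantile",
           lo_open = TRUE)
  in_range(cfg$aggclust$k_init, 1, Inf, "aggclust$k_init")
  in_range(cfg$aggclust$restarts, 1, Inf, "aggclust$restarts")
  if (!cfg$aggclust$reference_mode %in% c("hierarchical", "direction")) {
    abort("configuration field `aggclust$reference_mode` out of range")
  }
  in_range(cfg$lps$p_lo, 0, 1, "lps$p_lo")
  in_range(cfg$lps$p_hi, 0, 1, "lps$p_hi")
  if (cfg$lps$p_lo >= cfg$lps$p_hi) abort("need lps$p_lo < lps$p_hi")
  in_range(cfg$clonality$n_top, 1, Inf, "clonality$n_top")
  in_range(cfg$clonality$min_overlap, 1, Inf, "clonality$min_overlap")
  in_range(cfg$clonality$max_mismatch_density, 0, 1,
           "clonality$max_mismatch_density")
  invisible(cfg)
}

stage_log <- function(stage, ...) {
  rlang::inform(paste0("[", stage, "] ", paste0(...)))
}

run_stage <- function(stage, manifest, fun) {
  tryCatch(fun(), error = function(e) {
    err <- rlang::error_cnd(
      message = paste0("pipeline stage `", stage, "` failed: ",
                       conditionMessage(e)))
    attr(err, "partial_manifest") <- manifest
    stop(err)
  })
}

add_output <- function(manifest, stage, path) {
  dplyr::bind_rows(manifest, tibble::tibble(
    file = basename(path), stage = stage,
    md5 = unname(tools::md5sum(path))
  ))
}

write_sidecar <- function(path, stage, params) {
  side <- paste0(path, ".meta.json")
  jsonlite::write_json(list(stage = stage, parameters = params), side,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  side
}

#' Run the end-to-end expression-signature pipeline
#'
#' Chains the transcriptomic stages: mouse differential expression,
#' k-means cluster aggregation, human differential expression, ortholog
#' mapping and sign-coherent signature extraction with branch coherency,
#' and LPS classifier fitting on the human reference cohort with
#' prediction on the validation cohort. Every intermediate is written to
#' `paths$outdir` with a JSON sidecar naming the producing stage and its
#' parameters, and a manifest of file MD5 hashes is emitted; identical
#' configuration and inputs yield identical manifests.
#'
#' @param config A `pipeline_config` (see [load_config()]).
#' @return The manifest tibble (`file`, `stage`, `md5`), invisibly.
#' @export
run_expression_pipeline <- function(config) {
  p <- config$paths
  need <- c("mouse_matrix", "mouse_annot", "human_matrix", "human_annot",
            "validation_matrix", "validation_annot", "outdir")
  for (f in need) {
    if (is.null(p[[f]])) abort(paste0("missing required path field `", f, "`"))
  }
  for (f in setdiff(need, "outdir")) {
    if (!file.exists(p[[f]])) abort(paste0("path field `", f, "` does not exist: ", p[[f]]))
  }
  ct <- config$contrasts
  for (f in c("mouse_control", "mouse_case", "human_positive")) {
    if (is.null(ct[[f]])) abort(paste0("missing required contrast field `", f, "`"))
  }
  dir.create(p$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble(file = character(), stage = character(),
                             md5 = character())
  out <- function(f) file.path(p$outdir, f)

  cfg_path <- out("config_resolved.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- add_output(manifest, "config", cfg_path)

  mouse <- read_expression_tsv(p$mouse_matrix)
  mouse_annot <- read_annotation_tsv(p$mouse_annot)
  human <- read_expression_tsv(p$human_matrix)
  human_annot <- read_annotation_tsv(p$human_annot)
  valid <- read_expression_tsv(p$validation_matrix)

  d <- config$diffexpr
  stage_log("de", "mouse contrast ", ct$mouse_case, " vs ", ct$mouse_control)
  mouse_de <- run_stage("de", manifest, function() {
    differential_expression(mouse, mouse_annot, ct$mouse_control, ct$mouse_case,
                            d$fc_threshold, d$alpha, d$heterogeneity_quantile,
                            d$prior_df, d$prior_var)
  })
  f <- out("de_mouse.tsv")
  readr::write_tsv(mouse_de, f, progress = FALSE)
  write_sidecar(f, "de", d)
  manifest <- add_output(manifest, "de", f)

  stage_log("aggregate", "k_init = ", config$aggclust$k_init)
  agg <- run_stage("aggregate", manifest, function() {
    sel <- mouse_de$gene_id[mouse_de$selected]
    state <- initial_kmeans(mouse, k_init = config$aggclust$k_init,
                            seed = config$seed + 11L,
                            restarts = config$aggclust$restarts, genes = sel)
    aggregate_clusters(state, config$aggclust$reference_mode, de = mouse_de)
  })
  f <- out("clusters.tsv")
  readr::write_tsv(tidy(agg), f, progress = FALSE)
  write_sidecar(f, "aggregate", config$aggclust)
  manifest <- add_output(manifest, "aggregate", f)
  f <- out("merge_trace.tsv")
  readr::write_tsv(agg$trace, f, progress = FALSE)
  manifest <- add_output(manifest, "aggregate", f)

  stage_log("signature", "human positive class ", ct$human_positive)
  sig <- run_stage("signature", manifest, function() {
    human_cl <- setNames(ifelse(human_annot$class == ct$human_positive,
                                ct$human_positive, "other"),
                         human_annot$sample_id)
    human_de <- differential_expression(human, human_cl, "other",
                                        ct$human_positive,
                                        d$fc_threshold, d$alpha,
                                        d$heterogeneity_quantile,
                                        d$prior_df, d$prior_var)
    pairs <- map_orthologs(mouse_de$gene_id[mouse_de$selected], human_de$gene_id)
    signature <- coherent_signature(mouse_de, human_de, pairs)
    coh <- branch_coherency(mouse, human, signature,
                            mouse_annot, c(ct$mouse_control, ct$mouse_case),
                            human_cl, c("other", ct$human_positive))
    list(signature = signature, human_de = human_de, human_cl = human_cl,
         coherency = coh)
  })
  f <- out("de_human.tsv")
  readr::write_tsv(sig$human_de, f, progress = FALSE)
  manifest <- add_output(manifest, "signature", f)
  f <- out("signature.tsv")
  readr::write_tsv(tibble::as_tibble(sig$signature), f, progress = FALSE)
  write_sidecar(f, "signature", list(n_up = attr(sig$signature, "n_up"),
                                     n_down = attr(sig$signature, "n_down")))
  manifest <- add_output(manifest, "signature", f)
  f <- out("branch_overlap.json")
  jsonlite::write_json(signature_overlap(sig$coherency), f, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- add_output(manifest, "signature", f)

  stage_log("lps", "fit on reference cohort, predict validation cohort")
  lps <- run_stage("lps", manifest, function() {
    genes <- sig$signature$human_gene
    if (length(genes) == 0) abort("empty signature; cannot fit the classifier")
    if (!is.null(config$lps$max_genes)) {
      ref <- refine_predictor(human, sig$human_cl, ct$human_positive, genes,
                              max_genes = config$lps$max_genes,
                              p_hi = config$lps$p_hi, p_lo = config$lps$p_lo)
      model <- ref$model
    } else {
      model <- fit_lps(human, sig$human_cl, ct$human_positive, genes,
                       p_hi = config$lps$p_hi, p_lo = config$lps$p_lo)
    }
    list(model = model, pred = predict(model, valid))
  })
  f <- out("lps_model.json")
  write_lps_model(lps$model, f)
  manifest <- add_output(manifest, "lps", f)
  f <- out("predictions.tsv")
  readr::write_tsv(lps$pred, f, progress = FALSE)
  write_sidecar(f, "lps", config$lps)
  manifest <- add_output(manifest, "lps", f)

  f <- out("manifest.json")
  jsonlite::write_json(manifest, f, digits = NA, pretty = TRUE)
  stage_log("done", nrow(manifest), " outputs in ", p$outdir)
  invisible(manifest)
}

#' Run the end-to-end repertoire clonality pipeline
#'
#' From an AIRR rearrangement table (or FASTQ read pairs plus barcode and
#' primer tables, which are merged and demultiplexed first), builds
#' clonotype tables, per-library top-clone frequency reports, dominant
#' membrane/secreted clone matching, and — when a sample-group table is
#' supplied — an exact rank-sum comparison of dominant-clone frequencies
#' between groups per chain and isoform.
#'
#' @param config A `pipeline_config`; uses `paths$airr` or
#'   `paths$fastq_r1`/`fastq_r2` + `barcode_table`/`primer_table`, plus
#'   optional `paths$rep_groups` (TSV: `sample_id`, `group`).
#' @return The manifest tibble, invisibly.
#' @export
run_clonality_pipeline <- function(config) {
  p <- config$paths
  if (is.null(p$outdir)) abort("missing required path field `outdir`")
  dir.create(p$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble(file = character(), stage = character(),
                             md5 = character())
  out <- function(f) file.path(p$outdir, f)
  cc <- config$clonality

  cfg_path <- out("config_resolved.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- add_output(manifest, "config", cfg_path)

  if (!is.null(p$airr)) {
    stage_log("input", "AIRR table supplied; skipping merge and demultiplex")
    records <- read_airr_tsv(p$airr)
    if (nrow(records) == 0) abort("empty AIRR table")
  } else {
    for (f in c("fastq_r1", "fastq_r2", "barcode_table", "primer_table")) {
      if (is.null(p[[f]])) abort(paste0("missing required path field `", f, "`"))
    }
    stage_log("merge", "merging read pairs")
    merged <- run_stage("merge", manifest, function() {
      merge_read_pairs(read_fastq(p$fastq_r1), read_fastq(p$fastq_r2),
                       cc$min_overlap, cc$max_mismatch_density)
    })
    stage_log("demultiplex", "assigning reads to libraries")
    records <- run_stage("demultiplex", manifest, function() {
      demultiplex(merged,
                  readr::read_tsv(p$barcode_table, show_col_types = FALSE),
                  readr::read_tsv(p$primer_table, show_col_types = FALSE))
    })
  }

  stage_log("clonotypes", "building clonotype tables")
  clonotypes <- run_stage("clonotypes", manifest, function() {
    build_clonotypes(records, count_mode = cc$count_mode)
  })
  f <- out("clonotypes.tsv")
  readr::write_tsv(clonotypes, f, progress = FALSE)
  write_sidecar(f, "clonotypes", list(count_mode = cc$count_mode))
  manifest <- add_output(manifest, "clonotypes", f)

  stage_log("frequencies", "top-", cc$n_top, " clone frequencies per library")
  report <- top_clone_frequencies(clonotypes, n_top = cc$n_top)
  f <- out("top_clones.tsv")
  readr::write_tsv(report, f, progress = FALSE)
  write_sidecar(f, "frequencies", list(n_top = cc$n_top))
  manifest <- add_output(manifest, "frequencies", f)

  matches <- dominant_matches(report)
  f <- out("dominant_matches.tsv")
  readr::write_tsv(matches, f, progress = FALSE)
  manifest <- add_output(manifest, "matching", f)

  if (!is.null(p$rep_groups)) {
    stage_log("ranksum", "group comparison of dominant-clone frequencies")
    groups <- readr::read_tsv(p$rep_groups, show_col_types = FALSE)
    dom <- report[report$rank == 1, ]
    dom$group <- groups$group[match(dom$sample_id, groups$sample_id)]
    gl <- sort(unique(dom$group))
    if (length(gl) != 2) abort("rep_groups must define exactly 2 groups")
    tests <- dom |>
      dplyr::group_by(.data$chain, .data$isoform) |>
      dplyr::group_modify(function(d, key) {
        res <- ranksum_exact(d$frequency[d$group == gl[1]],
                             d$frequency[d$group == gl[2]])
        tibble::tibble(group_a = gl[1], group_b = gl[2],
                       n_a = sum(d$group == gl[1]), n_b = sum(d$group == gl[2]),
                       statistic = unname(res$statistic), p = res$p.value)
      }) |>
      dplyr::ungroup()
    f <- out("group_comparison.json")
    jsonlite::write_json(tests, f, digits = NA, pretty = TRUE)
    manifest <- add_output(manifest, "ranksum", f)
  }

  f <- out("manifest.json")
  jsonlite::write_json(manifest, f, digits = NA, pretty = TRUE)
  stage_log("done", nrow(manifest), " outputs in ", p$outdir)
  invisible(manifest)
}
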