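#' Simulate a two-group expression cohort with planted gene clusters
#'
#' Generates a log2 expression matrix emulating a small bulk microarray
#' cohort (e.g. three control and four tumor mice): per-gene baselines are
#' drawn once from a normal law and shared across samples, i.i.d. normal
#' noise is added per cell, and each planted cluster of co-regulated genes
#' is shifted by a signed log2 effect in the affected class. Genes outside
#' the planted clusters carry no class effect.
#'
#' @param n_genes Total number of genes.
#' @param cluster_spec Data frame with columns `size`, `effect` (positive
#'   log2 shift) and `direction` (`"up"` or `"down"`); one row per planted
#'   cluster. May be `NULL` for a pure-null cohort.
#' @param classes Data frame with columns `label` and `n` (samples per
#'   class); at least two classes of two samples each.
#' @param affected_class Class label carrying the planted effects; defaults
#'   to the last class listed.
#' @param noise_sd Standard deviation of the per-cell log2 noise.
#' @param baseline_mean,baseline_sd Normal law for per-gene baselines.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `expr` (tibble: `gene_id` + sample columns), `annot`
#'   (tibble: `sample_id`, `class`, `species`), and `truth` (list:
#'   `planted_cluster_of_gene`, `class_of_sample`,
#'   `effect_size_of_cluster`, `n_true_clusters`).
#' @examples
#' sim <- simulate_expression_cohort(
#'   n_genes = 100,
#'   cluster_spec = data.frame(size = 10, effect = 2, direction = "up"),
#'   classes = data.frame(label = c("WT", "MUT"), n = c(3, 4)),
#'   seed = 1
#' )
#' dim(sim$expr)
#' @export
simulate_expression_cohort <- function(n_genes, cluster_spec, classes,
                                       affected_class = NULL,
                                       noise_sd = 0.5,
                                       baseline_mean = 7, baseline_sd = 1.5,
                                       seed = 1) {
  classes <- tibble::as_tibble(classes)
  if (nrow(classes) < 2) abort("at least 2 classes are required")
  if (any(classes$n < 2)) abort("each class needs at least 2 samples (variance undefined below)")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (is.null(cluster_spec)) {
    cluster_spec <- tibble::tibble(size = integer(), effect = numeric(), direction = character())
  }
  cluster_spec <- tibble::as_tibble(cluster_spec)
  if (nrow(cluster_spec) > 0 && sum(cluster_spec$size) > n_genes) {
    abort("cluster sizes exceed n_genes")
  }
  affected_class <- affected_class %||% classes$label[nrow(classes)]
  if (!affected_class %in% classes$label) abort("affected_class not among class labels")

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- unlist(purrr::map2(classes$label, classes$n, function(l, n) {
    paste0(l, "_", seq_len(n))
  }))
  class_of_sample <- rep(classes$label, classes$n)
  names(class_of_sample) <- sample_ids

  # contiguous block assignment of genes to planted clusters
  planted <- rep(NA_integer_, n_genes)
  signed_effect <- numeric(0)
  if (nrow(cluster_spec) > 0) {
    stops <- cumsum(cluster_spec$size)
    starts <- c(1, head(stops, -1) + 1)
    for (c_i in seq_len(nrow(cluster_spec))) {
      planted[starts[c_i]:stops[c_i]] <- c_i
    }
    signed_effect <- cluster_spec$effect *
      ifelse(cluster_spec$direction == "down", -1, 1)
  }

  m <- withr::with_seed(seed, {
    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    x <- matrix(rnorm(n_genes * length(sample_ids), sd = noise_sd),
                nrow = n_genes) + baseline
    affected <- class_of_sample == affected_class
    for (c_i in seq_along(signed_effect)) {
      rows <- which(planted == c_i)
      if (signed_effect[c_i] != 0) {
        x[rows, affected] <- x[rows, affected] + signed_effect[c_i]
      }
    }
    x
  })
  dimnames(m) <- list(gene_ids, sample_ids)

  list(
    expr = matrix_to_expr(m),
    annot = tibble::tibble(sample_id = sample_ids,
                           class = unname(class_of_sample),
                           species = "mouse"),
    truth = list(
      planted_cluster_of_gene = setNames(planted, gene_ids),
      class_of_sample = class_of_sample,
      effect_size_of_cluster = setNames(signed_effect, seq_along(signed_effect)),
      n_true_clusters = nrow(cluster_spec),
      affected_class = affected_class
    )
  )
}

#' Simulate gene clusters with planted mean profiles
#'
#' Generates genes whose expression profiles across samples follow one of k
#' planted shape vectors plus i.i.d. normal noise — the substrate for
#' testing profile-based clustering and agglomeration. Shapes are
#' zero-mean, unit-norm vectors built from an orthonormal contrast basis
#' and a shape correlation matrix, so the pairwise geometry of the planted
#' centroids (and hence which clusters are closest) is controlled exactly.
#' The default three-cluster geometry uses unequal sizes and unequal
#' inter-cluster distances, the generic situation for co-regulation
#' modules.
#'
#' @param sizes Genes per cluster (default `c(30, 20, 10)`).
#' @param shape_cor Correlation matrix between cluster shapes; default (for
#'   3 clusters) puts clusters 1 and 2 closest and 1 and 3 farthest.
#' @param n_samples Number of samples (default 8).
#' @param scale Multiplier of the shape vectors (signal strength).
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return A list with `expr` (tibble) and `truth` (planted cluster per
#'   gene, shape matrix).
#' @export
simulate_profile_clusters <- function(sizes = c(30, 20, 10),
                                      shape_cor = NULL,
                                      n_samples = 8,
                                      scale = 2, noise_sd = 0.35,
                                      seed = 1) {
  k <- length(sizes)
  if (n_samples <= k) abort("need more samples than clusters")
  if (is.null(shape_cor)) {
    if (k == 3) {
      shape_cor <- matrix(c(1, 0.5, -0.5,
                            0.5, 1, 0.28,
                            -0.5, 0.28, 1), 3, 3)
    } else {
      shape_cor <- diag(k)
    }
  }
  # orthonormal zero-mean contrast basis (Helmert), rows 1..k
  h <- stats::contr.helmert(n_samples)
  h <- t(h) / sqrt(colSums(h^2))
  shapes <- t(chol(shape_cor)) %*% h[seq_len(k), , drop = FALSE]

  n_genes <- sum(sizes)
  cluster <- rep(seq_len(k), sizes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  m <- withr::with_seed(seed, {
    scale * shapes[cluster, , drop = FALSE] +
      matrix(rnorm(n_genes * n_samples, sd = noise_sd), nrow = n_genes)
  })
  dimnames(m) <- list(gene_ids, sprintf("s%02d", seq_len(n_samples)))
  list(
    expr = matrix_to_expr(m),
    truth = list(planted_cluster_of_gene = setNames(cluster, gene_ids),
                 shapes = shapes)
  )
}

#' Simulate paired mouse and human cohorts sharing a planted signature
#'
#' Emulates the cross-species design in which mouse tumors are compared with
#' human Waldenstrom macroglobulinemia (WM) cohorts: `signature_size` genes
#' carry class effects of the same sign in both species, except for a
#' fraction `discordance_rate` whose human sign is flipped. The human cohort
#' may contain more than two classes; only the designated positive class
#' carries the signature. Ortholog pairing follows the symbol convention
#' (mouse title-case, human upper-case).
#'
#' @param signature_size Number of signature genes (> 0).
#' @param discordance_rate Fraction of signature genes whose human effect
#'   sign is flipped, in \[0, 1\].
#' @param mouse_classes,human_classes Data frames with `label`, `n`.
#' @param mouse_positive,human_positive Class labels carrying the signature;
#'   default to the last class of each list.
#' @param effect Positive log2 effect size of signature genes.
#' @param noise_sd Per-cell noise standard deviation.
#' @param n_background Non-signature genes added to both matrices.
#' @param seed Integer seed.
#' @return A list with `mouse`, `mouse_annot`, `human`, `human_annot`, and a
#'   shared `truth` holding the per-gene signed effects for both species
#'   (`signature`: tibble with `mouse_gene`, `human_gene`, `mouse_sign`,
#'   `human_sign`, `discordant`).
#' @export
simulate_paired_species <- function(signature_size, discordance_rate,
                                    mouse_classes, human_classes,
                                    effect = 2, noise_sd = 0.5,
                                    n_background = 100,
                                    mouse_positive = NULL,
                                    human_positive = NULL,
                                    seed = 1) {
  if (signature_size <= 0) abort("signature_size must be positive")
  if (discordance_rate < 0 || discordance_rate > 1) {
    abort("discordance_rate must lie in [0, 1]")
  }
  mouse_classes <- tibble::as_tibble(mouse_classes)
  human_classes <- tibble::as_tibble(human_classes)
  mouse_positive <- mouse_positive %||% mouse_classes$label[nrow(mouse_classes)]
  human_positive <- human_positive %||% human_classes$label[nrow(human_classes)]

  truth <- withr::with_seed(seed, {
    mouse_sign <- sample(c(1, -1), signature_size, replace = TRUE)
    flip <- rbinom(signature_size, 1, discordance_rate) == 1
    tibble::tibble(
      mouse_gene = sprintf("Sig%04d", seq_len(signature_size)),
      human_gene = sprintf("SIG%04d", seq_len(signature_size)),
      mouse_sign = mouse_sign,
      human_sign = ifelse(flip, -mouse_sign, mouse_sign),
      discordant = flip
    )
  })

  n_genes <- signature_size + n_background
  gene_tbl <- withr::with_seed(seed + 53L, tibble::tibble(
    mouse_gene = c(truth$mouse_gene, sprintf("Bgrd%04d", seq_len(n_background))),
    human_gene = c(truth$human_gene, sprintf("BGRD%04d", seq_len(n_background))),
    mouse_sign = c(truth$mouse_sign, rep(0, n_background)),
    human_sign = c(truth$human_sign, rep(0, n_background)),
    # per-gene platform baselines, shared by every cohort drawn from this
    # truth (the same gene keeps its average expression across cohorts)
    mouse_baseline = rnorm(n_genes, 7, 1.5),
    human_baseline = rnorm(n_genes, 7, 1.5)
  ))

  mouse <- build_species_matrix(gene_tbl$mouse_gene, gene_tbl$mouse_sign * effect,
                                mouse_classes, mouse_positive, noise_sd,
                                species = "mouse", seed = seed + 101L,
                                baseline = gene_tbl$mouse_baseline)
  human <- build_species_matrix(gene_tbl$human_gene, gene_tbl$human_sign * effect,
                                human_classes, human_positive, noise_sd,
                                species = "human", seed = seed + 202L,
                                baseline = gene_tbl$human_baseline)

  list(
    mouse = mouse$expr, mouse_annot = mouse$annot,
    human = human$expr, human_annot = human$annot,
    truth = list(
      signature = truth,
      genes = gene_tbl,
      effect = effect, noise_sd = noise_sd,
      mouse_positive = mouse_positive, human_positive = human_positive
    )
  )
}

#' Simulate an additional human cohort from a paired-species truth
#'
#' Draws a fresh human-like cohort (new baselines, new noise) whose
#' signature genes carry the signed effects recorded in the `truth` of
#' [simulate_paired_species()]. Used to create disjoint training and
#' validation cohorts sharing the same planted signature, e.g. a 58-sample
#' multi-entity validation series.
#'
#' @param truth The `truth` element returned by [simulate_paired_species()].
#' @param classes Data frame with `label`, `n` columns.
#' @param positive_class Class label carrying the signature; defaults to the
#'   truth's recorded human positive class.
#' @param noise_sd Noise standard deviation; defaults to the truth's value.
#' @param seed Integer seed.
#' @return A list with `expr` and `annot` tibbles.
#' @export
simulate_human_cohort <- function(truth, classes, positive_class = NULL,
                                  noise_sd = NULL, seed = 1) {
  classes <- tibble::as_tibble(classes)
  positive_class <- positive_class %||% truth$human_positive
  noise_sd <- noise_sd %||% truth$noise_sd
  build_species_matrix(truth$genes$human_gene,
                       truth$genes$human_sign * truth$effect,
                       classes, positive_class, noise_sd,
                       species = "human", seed = seed,
                       baseline = truth$genes$human_baseline)
}

build_species_matrix <- function(gene_ids, signed_effects, classes,
                                 positive_class, noise_sd, species, seed,
                                 baseline = NULL,
                                 baseline_mean = 7, baseline_sd = 1.5) {
  if (!positive_class %in% classes$label) {
    abort(paste0("positive class '", positive_class, "' not among class labels"))
  }
  sample_ids <- unlist(purrr::map2(classes$label, classes$n, function(l, n) {
    paste0(l, "_", seq_len(n))
  }))
  class_of_sample <- rep(classes$label, classes$n)
  m <- withr::with_seed(seed, {
    if (is.null(baseline)) {
      baseline <- rnorm(length(gene_ids), baseline_mean, baseline_sd)
    }
    x <- matrix(rnorm(length(gene_ids) * length(sample_ids), sd = noise_sd),
                nrow = length(gene_ids)) + baseline
    pos <- class_of_sample == positive_class
    x[, pos] <- x[, pos] + signed_effects
    x
  })
  dimnames(m) <- list(gene_ids, sample_ids)
  list(
    expr = matrix_to_expr(m),
    annot = tibble::tibble(sample_id = sample_ids, class = class_of_sample,
                           species = species)
  )
}

#' Simulate immunoglobulin heavy-chain repertoire libraries
#'
#' For each sample and chain, two isoform libraries (membrane and secreted)
#' are drawn multinomially. Clonal samples put probability `dominant_freq`
#' on one clonotype whose key is shared between the membrane and secreted
#' libraries of that sample and chain — mirroring the observation that tumor
#' mice express secreted and membrane mu transcripts with the same VDJ
#' rearrangement. The remaining probability mass is spread geometrically
#' over background clones drawn independently per library; polyclonal
#' samples (and chains outside `clonal_chains`) use the background
#' distribution only.
#'
#' @param samples Data frame with columns `sample_id`, `is_clonal`,
#'   `dominant_freq` (in (0, 1) for clonal samples).
#' @param n_background_clones Background clones per library.
#' @param n_reads Reads per library (>= 100).
#' @param chains Character subset of `c("mu", "gamma")`.
#' @param clonal_chains Chains in which clonal samples are actually clonal
#'   (default `"mu"`: IgM but not IgG clonal expansion).
#' @param head_prob Geometric head probability of the background
#'   rank-abundance decay.
#' @param seed Integer seed.
#' @param emit_fastq If `TRUE`, also write paired overlapping FASTQ reads
#'   (plus barcode and primer tables) under `fastq_dir`.
#' @param fastq_dir Directory for FASTQ output when `emit_fastq = TRUE`.
#' @param read_length Read length for FASTQ emission.
#' @param reads_per_library Reads written per library when emitting FASTQ
#'   (kept separate from `n_reads` so count tables stay cheap to simulate).
#' @return A list with `clonotypes` (AIRR-style tibble with `sequence_id`,
#'   `v_call`, `j_call`, `junction`, `duplicate_count`, `sequence`,
#'   `sample_id`, `chain`, `isoform`), `truth` (planted dominant frequencies
#'   and keys), `barcode_table`, `primer_table`, and — when FASTQ is emitted
#'   — `fastq_r1`, `fastq_r2` paths.
#' @export
simulate_repertoire <- function(samples, n_background_clones = 50,
                                n_reads = 10000,
                                chains = c("mu", "gamma"),
                                clonal_chains = "mu",
                                head_prob = 0.05,
                                seed = 1,
                                emit_fastq = FALSE, fastq_dir = NULL,
                                read_length = 60,
                                reads_per_library = 300) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "is_clonal") %in% names(samples)))
  if (!"dominant_freq" %in% names(samples)) samples$dominant_freq <- NA_real_
  if (n_reads < 100) abort("n_reads must be at least 100")
  clonal <- samples$is_clonal
  bad <- clonal & (is.na(samples$dominant_freq) |
                     samples$dominant_freq <= 0 | samples$dominant_freq >= 1)
  if (any(bad)) abort("dominant_freq must lie in (0, 1) for clonal samples")

  chains <- match.arg(chains, c("mu", "gamma"), several.ok = TRUE)
  isoforms <- c("membrane", "secreted")

  res <- withr::with_seed(seed, {
    barcodes <- random_distinct_seqs(nrow(samples), 8)
    primer_tbl <- tidyr::expand_grid(chain = chains, isoform = isoforms)
    primer_tbl$primer <- random_distinct_seqs(nrow(primer_tbl), 20)

    rows <- list()
    truth_freq <- list()
    truth_key <- list()
    for (s_i in seq_len(nrow(samples))) {
      sid <- samples$sample_id[s_i]
      for (ch in chains) {
        sample_clonal <- clonal[s_i] && ch %in% clonal_chains
        dom <- if (sample_clonal) make_clonotype(ch) else NULL
        if (sample_clonal) {
          truth_key[[paste(sid, ch, sep = "|")]] <- clonotype_key(dom)
        }
        for (iso in isoforms) {
          lib_id <- paste(sid, ch, iso, sep = "|")
          bg <- purrr::map(seq_len(n_background_clones), function(i) make_clonotype(ch))
          w <- head_prob * (1 - head_prob)^(seq_len(n_background_clones) - 1)
          w <- w / sum(w)
          if (sample_clonal) {
            p <- c(samples$dominant_freq[s_i], (1 - samples$dominant_freq[s_i]) * w)
            clones <- c(list(dom), bg)
            truth_freq[[lib_id]] <- samples$dominant_freq[s_i]
          } else {
            p <- w
            clones <- bg
            truth_freq[[lib_id]] <- NA_real_
          }
          counts <- as.integer(stats::rmultinom(1, n_reads, p))
          keep <- counts > 0
          tab <- purrr::list_rbind(clones[keep])
          tab$duplicate_count <- counts[keep]
          tab$sample_id <- sid
          tab$chain <- ch
          tab$isoform <- iso
          rows[[lib_id]] <- tab
        }
      }
    }
    clonotypes <- purrr::list_rbind(rows)
    clonotypes$sequence_id <- sprintf("seq%06d", seq_len(nrow(clonotypes)))
    clonotypes <- clonotypes[, c("sequence_id", "v_call", "j_call", "junction",
                                 "duplicate_count", "sequence",
                                 "sample_id", "chain", "isoform")]
    list(
      clonotypes = clonotypes,
      barcode_table = tibble::tibble(barcode = barcodes,
                                     sample_id = samples$sample_id),
      primer_table = primer_tbl,
      truth = list(
        dominant_freq_of_library = truth_freq,
        dominant_key_of_sample = truth_key,
        is_clonal = setNames(clonal, samples$sample_id)
      )
    )
  })

  if (emit_fastq) {
    if (is.null(fastq_dir)) abort("fastq_dir is required when emit_fastq = TRUE")
    dir.create(fastq_dir, recursive = TRUE, showWarnings = FALSE)
    fq <- withr::with_seed(seed + 7L, {
      emit_repertoire_fastq(res$clonotypes, res$barcode_table, res$primer_table,
                            read_length, reads_per_library)
    })
    r1 <- file.path(fastq_dir, "reads_R1.fastq")
    r2 <- file.path(fastq_dir, "reads_R2.fastq")
    write_fastq(fq$r1, r1)
    write_fastq(fq$r2, r2)
    res$fastq_r1 <- r1
    res$fastq_r2 <- r2
  }
  res
}

# one random clonotype: V/J gene calls plus a junction; full-length
# transcript sequence is V flank + junction + J flank
make_clonotype <- function(chain) {
  prefix <- if (chain == "mu") "IGHV" else "IGHV"
  v <- paste0(prefix, sample(1:15, 1), "-", sample(1:80, 1))
  j <- paste0("IGHJ", sample(1:4, 1))
  junction <- random_seq(3 * sample(6:10, 1))
  tibble::tibble(
    v_call = v, j_call = j, junction = junction,
    sequence = paste0(random_seq(25), junction, random_seq(18))
  )
}

clonotype_key <- function(row) {
  paste(row$v_call, row$j_call, row$junction, sep = "|")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_distinct_seqs <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, random_seq(len)))
  }
  out[seq_len(n)]
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Down-sampled paired reads per library, proportional to clone frequencies.
emit_repertoire_fastq <- function(clonotypes, barcode_table, primer_table,
                                  read_length, reads_per_library) {
  ids <- character(0); seq1 <- character(0); seq2 <- character(0)
  libs <- dplyr::group_split(dplyr::group_by(clonotypes, .data$sample_id,
                                             .data$chain, .data$isoform))
  for (lib in libs) {
    bc <- barcode_table$barcode[match(lib$sample_id[1], barcode_table$sample_id)]
    pr <- primer_table$primer[primer_table$chain == lib$chain[1] &
                                primer_table$isoform == lib$isoform[1]]
    n_per_clone <- as.integer(stats::rmultinom(
      1, reads_per_library, lib$duplicate_count / sum(lib$duplicate_count)))
    for (c_i in which(n_per_clone > 0)) {
      template <- paste0(bc, pr, lib$sequence[c_i])
      tl <- nchar(template)
      rl <- min(read_length, tl)
      fwd <- substr(template, 1, rl)
      rev <- revcomp(substr(template, tl - rl + 1, tl))
      rid <- paste0(lib$sample_id[1], ":", lib$chain[1], ":", lib$isoform[1],
                    ":", lib$sequence_id[c_i], ":", seq_len(n_per_clone[c_i]))
      ids <- c(ids, rid)
      seq1 <- c(seq1, rep(fwd, n_per_clone[c_i]))
      seq2 <- c(seq2, rep(rev, n_per_clone[c_i]))
    }
  }
  q <- function(s) strrep("I", nchar(s))
  list(
    r1 = tibble::tibble(read_id = ids, sequence = seq1, quality = q(seq1)),
    r2 = tibble::tibble(read_id = ids, sequence = seq2, quality = q(seq2))
  )
}
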