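test_that("expression cohorts are seed-deterministic with the designed shape", {
  spec <- data.frame(size = c(10, 5), effect = c(2, 1.5),
                     direction = c("up", "down"))
  classes <- data.frame(label = c("WT", "MUT"), n = c(3, 4))
  a <- simulate_expression_cohort(100, spec, classes, seed = 7)
  b <- simulate_expression_cohort(100, spec, classes, seed = 7)
  expect_identical(a, b)
  expect_equal(ncol(a$expr) - 1, 7)
  expect_equal(nrow(a$expr), 100)
  expect_equal(unname(table(a$annot$class)[c("WT", "MUT")]), c(3L, 4L),
               ignore_attr = TRUE)
  c_ <- simulate_expression_cohort(100, spec, classes, seed = 8)
  expect_false(identical(a$expr, c_$expr))
})

test_that("cohort truth records planted clusters and class labels exactly once", {
  sim <- small_cohort(seed = 3, n_planted = 20)
  tr <- sim$truth
  expect_equal(sum(!is.na(tr$planted_cluster_of_gene)), 20)
  planted <- which(!is.na(tr$planted_cluster_of_gene))
  expect_true(all(tr$effect_size_of_cluster[
    tr$planted_cluster_of_gene[planted]] != 0))
  expect_setequal(names(tr$class_of_sample), sim$annot$sample_id)
  # planted genes actually shifted, background not
  lfc <- log2_fold_changes(sim$expr, sim$annot, "WT", "MUT")
  expect_gt(mean(lfc$log2fc[planted]), 2)
  expect_lt(abs(mean(lfc$log2fc[-planted])), 0.5)
})

test_that("cohort generator rejects invalid designs", {
  classes <- data.frame(label = c("A", "B"), n = c(3, 4))
  expect_error(simulate_expression_cohort(
    5, data.frame(size = 10, effect = 1, direction = "up"), classes),
    "exceed")
  expect_error(simulate_expression_cohort(
    10, NULL, data.frame(label = c("A", "B"), n = c(1, 4))), "at least 2")
  expect_error(simulate_expression_cohort(10, NULL, data.frame(label = "A", n = 4)),
               "2 classes")
  expect_error(simulate_expression_cohort(10, NULL, classes, noise_sd = 0),
               "positive")
})

test_that("null cohorts are calibrated: raw p <= 0.05 near the nominal rate", {
  sim <- simulate_expression_cohort(
    1000, NULL, data.frame(label = c("A", "B"), n = c(4, 4)),
    seed = 11
  )
  de <- moderated_t(sim$expr, sim$annot, "A", "B")
  n_hits <- sum(de$p <= 0.05)
  band <- 3 * sqrt(0.05 * 0.95 * 1000)
  expect_lt(abs(n_hits - 50), band)
  # and the FDR-controlled selection stays near-empty under the global null
  sel <- suppressWarnings(select_de(de, fc_threshold = 1, alpha = 0.05,
                                    heterogeneity_quantile = 1))
  expect_lt(sum(sel$selected), band)
})

test_that("paired-species truth hits the requested discordance rate", {
  mc <- data.frame(label = c("WT", "MUT"), n = c(3, 4))
  hc <- data.frame(label = c("other", "WM"), n = c(5, 6))

  zero <- simulate_paired_species(50, 0, mc, hc, seed = 1)
  expect_true(all(zero$truth$signature$mouse_sign ==
                    zero$truth$signature$human_sign))

  fracs <- vapply(1:30, function(s) {
    sim <- simulate_paired_species(400, 0.05, mc, hc, n_background = 0, seed = s)
    mean(sim$truth$signature$discordant)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / 400) / sqrt(30)
  expect_lt(abs(mean(fracs) - 0.05), 3 * se)
})

test_that("paired-species human cohort carries the spec's multi-entity shape", {
  hc <- data.frame(label = c("CLL", "NMZL", "WM_WT", "FCL", "NT", "WM_L265P"),
                   n = c(19, 12, 5, 4, 3, 15))
  sim <- simulate_paired_species(
    30, 0, data.frame(label = c("WT", "MUT"), n = c(3, 4)), hc, seed = 2)
  expect_equal(ncol(sim$human) - 1, 58)
  expect_equal(sim$truth$human_positive, "WM_L265P")
  # mouse/human symbol convention is case-paired
  expect_equal(toupper(sim$truth$signature$mouse_gene),
               sim$truth$signature$human_gene)
  expect_error(simulate_paired_species(0, 0, hc, hc), "positive")
  expect_error(simulate_paired_species(10, 1.5, hc, hc), "0, 1")
})

test_that("simulate_human_cohort reuses the planted signature signs", {
  mc <- data.frame(label = c("WT", "MUT"), n = c(3, 4))
  hc <- data.frame(label = c("other", "WM"), n = c(4, 4))
  sim <- simulate_paired_species(40, 0, mc, hc, effect = 3, noise_sd = 0.3,
                                 seed = 5)
  val <- simulate_human_cohort(sim$truth, data.frame(label = c("x", "WM"),
                                                     n = c(6, 6)), seed = 9)
  lfc <- log2_fold_changes(val$expr, val$annot, "x", "WM")
  sig <- sim$truth$signature
  got <- sign(lfc$log2fc[match(sig$human_gene, lfc$gene_id)])
  expect_equal(got, sig$human_sign)
})

test_that("repertoire libraries conserve reads and share clonal keys across isoforms", {
  samples <- data.frame(sample_id = c("m1", "m2"), is_clonal = c(TRUE, FALSE),
                        dominant_freq = c(0.6, NA))
  rep <- simulate_repertoire(samples, n_background_clones = 30, n_reads = 1000,
                             seed = 4)
  counts <- dplyr::count(rep$clonotypes, sample_id, chain, isoform,
                         wt = duplicate_count)
  expect_true(all(counts$n == 1000))
  expect_equal(nrow(counts), 8) # 2 samples x 2 chains x 2 isoforms
  # clonal sample: same dominant clonotype key in membrane and secreted truth
  rep2 <- simulate_repertoire(samples, seed = 4)
  expect_identical(rep$truth, rep2$truth)
  report <- top_clone_frequencies(build_clonotypes(rep$clonotypes))
  expect_true(dominant_isoform_match(report, "m1", "mu"))
})

test_that("planted dominant frequency is recovered within binomial error", {
  samples <- data.frame(sample_id = "m1", is_clonal = TRUE, dominant_freq = 0.6)
  rep <- simulate_repertoire(samples, n_reads = 10000, chains = "mu", seed = 10)
  report <- top_clone_frequencies(build_clonotypes(rep$clonotypes))
  dom <- report$frequency[report$rank == 1]
  expect_true(all(abs(dom - 0.6) < 3 * sqrt(0.6 * 0.4 / 10000)))
})

test_that("polyclonal libraries show no dominant clone beyond the geometric head", {
  samples <- data.frame(sample_id = "p1", is_clonal = FALSE,
                        dominant_freq = NA)
  top <- vapply(1:20, function(s) {
    rep <- simulate_repertoire(samples, n_background_clones = 50,
                               n_reads = 2000, chains = "mu", seed = s)
    report <- top_clone_frequencies(build_clonotypes(rep$clonotypes))
    max(report$frequency[report$rank == 1])
  }, numeric(1))
  # geometric head probability is 0.05 (after truncation ~0.054)
  expect_true(all(top <= 3 * 0.054))
})

test_that("invalid repertoire requests are rejected", {
  expect_error(simulate_repertoire(
    data.frame(sample_id = "a", is_clonal = TRUE, dominant_freq = 1.2)),
    "dominant_freq")
  expect_error(simulate_repertoire(
    data.frame(sample_id = "a", is_clonal = FALSE), n_reads = 10),
    "at least 100")
})

test_that("matrix and annotation TSV round-trips are lossless", {
  sim <- small_cohort(seed = 2, n_genes = 30)
  tmp <- withr::local_tempdir()
  write_expression_tsv(sim$expr, file.path(tmp, "m.tsv"))
  write_annotation_tsv(sim$annot, file.path(tmp, "a.tsv"))
  expect_equal(read_expression_tsv(file.path(tmp, "m.tsv")), sim$expr)
  expect_equal(read_annotation_tsv(file.path(tmp, "a.tsv")), sim$annot)
  write_airr_tsv(tibble::tibble(sequence_id = "s1", v_call = "IGHV1-1",
                                j_call = "IGHJ4", junction = "TGTGCG",
                                duplicate_count = 3L, sample_id = "m1",
                                chain = "mu", isoform = "membrane"),
                 file.path(tmp, "r.tsv"))
  expect_equal(read_airr_tsv(file.path(tmp, "r.tsv"))$duplicate_count, 3)
})
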