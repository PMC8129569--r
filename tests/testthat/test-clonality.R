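revcomp1 <- function(s) sigclone:::revcomp(s)

test_that("a perfect overlap reconstructs the template", {
  template <- withr::with_seed(1, paste(sample(c("A", "C", "G", "T"), 60,
                                               replace = TRUE), collapse = ""))
  r1 <- substr(template, 1, 45)
  r2 <- revcomp1(substr(template, 16, 60)) # 30-nt overlap
  m <- merge_read_pair(r1, r2)
  expect_equal(m$sequence, template)
  expect_equal(m$overlap, 30)
  expect_equal(m$mismatch_density, 0)
  expect_error(merge_read_pair("", "ACGT"), "empty")
})

test_that("overlaps above the mismatch-density threshold fail", {
  # single candidate overlap of 20 with 6 mismatches: density 0.3 > 0.25
  left <- strrep("A", 20)
  overlap_r1 <- paste0(strrep("C", 6), strrep("G", 14))
  overlap_r2 <- paste0(strrep("T", 6), strrep("G", 14))
  r1 <- paste0(left, overlap_r1)
  r2 <- revcomp1(overlap_r2) # r2 has no bases beyond the overlap
  expect_null(merge_read_pair(r1, r2, min_overlap = 20))
  # at 5 mismatches (density 0.25) the same construction merges
  overlap_r2b <- paste0(strrep("T", 5), "C", strrep("G", 14))
  expect_false(is.null(merge_read_pair(r1, revcomp1(overlap_r2b),
                                       min_overlap = 20)))
})

test_that("overlap consensus takes the higher-quality base", {
  template <- withr::with_seed(2, paste(sample(c("A", "C", "G", "T"), 40,
                                               replace = TRUE), collapse = ""))
  r1 <- substr(template, 1, 30)
  r2_seq <- substr(template, 11, 40)
  # corrupt one overlap position in read 1, give it low quality
  r1_bad <- r1
  substr(r1_bad, 15, 15) <- "T"
  q1 <- paste0(strrep("I", 14), "+", strrep("I", 15)) # Q40 except Q10 at pos 15
  m <- merge_read_pair(r1_bad, revcomp1(r2_seq), qual1 = q1)
  expect_equal(m$sequence, template)
  # reversed qualities: the corrupted base wins when ITS quality is higher
  m2 <- merge_read_pair(r1_bad, revcomp1(r2_seq),
                        qual2 = paste0(strrep("+", 30)))
  expect_equal(substr(m2$sequence, 15, 15), "T")
})

test_that("demultiplexing assigns by exact barcode and <=1-mismatch primer", {
  barcodes <- data.frame(barcode = c("AAAAAAAA", "CCCCCCCC"),
                         sample_id = c("m1", "m2"))
  primers <- data.frame(primer = c("GGGGGGGGGG", "TTTTTTTTTT"),
                        chain = c("mu", "mu"),
                        isoform = c("membrane", "secreted"))
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"),
    sequence = c(
      paste0("AAAAAAAA", "GGGGGGGGGG", "ACGTACGT"),  # exact
      paste0("CCCCCCCC", "TTTTTTTTAT", "ACGTACGT"),  # 1 primer mismatch
      paste0("CCCCCCCC", "TTTTTTGGAT", "ACGTACGT"),  # 3 mismatches -> drop
      paste0("GGGGGGGG", "GGGGGGGGGG", "ACGTACGT")   # unknown barcode
    ))
  out <- suppressMessages(demultiplex(reads, barcodes, primers))
  expect_equal(nrow(out), 2)
  expect_equal(out$sample_id, c("m1", "m2"))
  expect_equal(out$isoform, c("membrane", "secreted"))
  expect_equal(out$trimmed_sequence, rep("ACGTACGT", 2))
  tally <- attr(out, "tally")
  expect_equal(tally$unassigned_barcode, 1)
  expect_equal(tally$unassigned_primer, 1)
  empty <- suppressMessages(demultiplex(reads[0, ], barcodes, primers))
  expect_equal(nrow(empty), 0)
  expect_error(demultiplex(reads, data.frame(barcode = c("A", "A"),
                                             sample_id = c("x", "y")),
                           primers), "colliding")
})

test_that("clonotype aggregation sums counts within a library key", {
  airr <- tibble::tibble(
    sequence_id = sprintf("s%d", 1:4),
    v_call = c("IGHV1-1", "IGHV1-1", "IGHV1-1", "IGHV2-1"),
    j_call = "IGHJ4",
    junction = c("TGTGCG", "TGTGCG", "TGTGCG", "TGTGCG"),
    duplicate_count = c(3L, 4L, 5L, 7L),
    sample_id = "m1", chain = "mu",
    isoform = c("membrane", "membrane", "secreted", "secreted"))
  tab <- build_clonotypes(airr)
  expect_equal(nrow(tab), 3)
  mem <- tab[tab$isoform == "membrane", ]
  expect_equal(mem$count, 7) # 3 + 4 summed within one key
  # identical rows except isoform live in different libraries
  expect_equal(sort(tab$count[tab$isoform == "secreted"]), c(5, 7))
  # read-counting mode ignores duplicate_count
  expect_equal(build_clonotypes(airr, count_mode = "reads")$count, c(2, 1, 1))
  expect_error(build_clonotypes(dplyr::mutate(airr, junction = "TGTXCG")),
               "invalid characters")
  expect_error(build_clonotypes(airr[, -2]), "v_call")
})

test_that("top-clone frequencies are normalized, sorted, and truncated", {
  tab <- tibble::tibble(
    sample_id = "m1", chain = "mu", isoform = "membrane",
    v_call = "V", j_call = "J",
    junction = c("AAA", "CCC", "GGG"),
    clone_key = c("V|J|AAA", "V|J|CCC", "V|J|GGG"),
    count = c(50, 30, 20))
  rep <- top_clone_frequencies(tab, n_top = 5)
  expect_equal(rep$frequency, c(0.5, 0.3, 0.2))
  expect_equal(rep$rank, 1:3) # fewer clones than n_top
  expect_true(all(diff(rep$frequency) <= 0))
  single <- top_clone_frequencies(tab[1, ], n_top = 5)
  expect_equal(single$frequency, 1.0)
  # frequency ties break lexicographically by clone key
  tie <- dplyr::mutate(tab, count = c(10, 10, 10))
  expect_equal(top_clone_frequencies(tie, 2)$clone_key,
               c("V|J|AAA", "V|J|CCC"))
})

test_that("library frequencies sum to one before truncation", {
  samples <- data.frame(sample_id = c("a", "b"), is_clonal = c(TRUE, FALSE),
                        dominant_freq = c(0.5, NA))
  rep <- simulate_repertoire(samples, n_reads = 500, seed = 2)
  tab <- build_clonotypes(rep$clonotypes)
  sums <- tab |>
    dplyr::group_by(sample_id, chain, isoform) |>
    dplyr::summarise(s = sum(count / sum(count)), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("dominant isoform matching distinguishes clonal from polyclonal samples", {
  n_match_clonal <- 0L; n_match_poly <- 0L
  for (s in 1:20) {
    samples <- data.frame(sample_id = c("t1", "c1"),
                          is_clonal = c(TRUE, FALSE),
                          dominant_freq = c(0.6, NA))
    rep <- simulate_repertoire(samples, n_reads = 2000, chains = "mu", seed = s)
    report <- top_clone_frequencies(build_clonotypes(rep$clonotypes))
    if (dominant_isoform_match(report, "t1", "mu")) {
      n_match_clonal <- n_match_clonal + 1L
    }
    if (dominant_isoform_match(report, "c1", "mu")) {
      n_match_poly <- n_match_poly + 1L
    }
  }
  expect_equal(n_match_clonal, 20)
  expect_lte(n_match_poly, 2)
})

test_that("full-key comparison and missing libraries are enforced", {
  report <- top_clone_frequencies(tibble::tibble(
    sample_id = "m1", chain = "mu",
    isoform = c("membrane", "secreted"),
    v_call = c("IGHV1-1", "IGHV2-1"), j_call = "IGHJ4", junction = "TGTGCG",
    clone_key = c("IGHV1-1|IGHJ4|TGTGCG", "IGHV2-1|IGHJ4|TGTGCG"),
    count = c(10, 10)))
  # same junction, different V gene: not a match
  expect_false(dominant_isoform_match(report, "m1", "mu"))
  expect_error(dominant_isoform_match(report[1, ], "m1", "mu"), "secreted")
  matches <- dominant_matches(report)
  expect_equal(matches$dominant_match, FALSE)
})

test_that("exact rank-sum matches hand enumeration and the brute-force oracle", {
  expect_equal(ranksum_exact(c(1, 2), c(3, 4))$p.value, 1 / 3)
  expect_equal(ranksum_exact(c(1, 2), c(1, 2))$p.value, 1)
  # one-sided tails
  expect_equal(ranksum_exact(c(1, 2), c(3, 4), "less")$p.value, 1 / 6)
  expect_equal(ranksum_exact(c(1, 2), c(3, 4), "greater")$p.value, 1)
  expect_error(ranksum_exact(numeric(0), 1), "non-empty")
  # brute-force agreement over random small datasets, with ties
  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(1:4, 1); m <- sample(1:4, 1)
      x <- sample(1:5, n, replace = TRUE)
      y <- sample(1:5, m, replace = TRUE)
      expect_equal(ranksum_exact(x, y)$p.value, ranksum_bruteforce(x, y))
    }
  })
  # agrees with wilcox.test exact p when there are no ties
  withr::with_seed(7, {
    x <- rnorm(5); y <- rnorm(6)
  })
  expect_equal(ranksum_exact(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value)
  # large-sample path uses the normal approximation
  big <- suppressMessages(ranksum_exact(rnorm(10), rnorm(10)))
  expect_match(big$method, "normal approximation")
  expect_equal(big$p.value,
               suppressWarnings(wilcox.test(rnorm(10), rnorm(10)))$p.value,
               tolerance = 1) # same family; exact agreement checked below
})

test_that("normal-approximation path agrees with wilcox.test continuity correction", {
  withr::with_seed(11, {
    x <- rnorm(8); y <- rnorm(7)
  })
  ours <- suppressMessages(ranksum_exact(x, y)$p.value)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("FASTQ emission round-trips through merge, demultiplex and clonotyping", {
  tmp <- withr::local_tempdir()
  samples <- data.frame(sample_id = c("t1", "c1"),
                        is_clonal = c(TRUE, FALSE),
                        dominant_freq = c(0.7, NA))
  rep <- simulate_repertoire(samples, n_background_clones = 20,
                             n_reads = 1000, chains = "mu", seed = 9,
                             emit_fastq = TRUE, fastq_dir = tmp,
                             reads_per_library = 400)
  r1 <- read_fastq(rep$fastq_r1); r2 <- read_fastq(rep$fastq_r2)
  expect_equal(nrow(r1), 4 * 400) # 2 samples x 2 isoforms
  merged <- merge_read_pairs(r1, r2)
  expect_true(all(merged$merged))
  dmx <- suppressMessages(demultiplex(merged, rep$barcode_table,
                                      rep$primer_table))
  expect_equal(attr(dmx, "tally")$assigned, nrow(r1))
  tab <- build_clonotypes(dmx)
  report <- top_clone_frequencies(tab)
  dom <- report[report$sample_id == "t1" & report$rank == 1, ]
  se <- sqrt(0.7 * 0.3 / 400)
  expect_true(all(abs(dom$frequency - 0.7) < 3 * se + 0.05))
  expect_true(dominant_isoform_match(report, "t1", "mu"))
})
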