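#' Merge one 5'RACE amplicon read pair by overlap consensus
#'
#' Read 2 is reverse-complemented, then candidate overlaps are scanned from
#' the longest possible down to `min_overlap`. Overlaps whose mismatch
#' fraction is at most `max_mismatch_density` qualify; among them the one
#' with the lowest mismatch density wins (ties resolved toward the longest
#' overlap). Within the overlap, each disagreeing position takes the base
#' with the higher Phred quality (ties take read 1). Returns `NULL` when no
#' overlap qualifies.
#'
#' @param read1,read2 Read sequences over `A,C,G,T,N` (read 2 in sequencing
#'   orientation).
#' @param qual1,qual2 Phred+33 quality strings; default maximal quality.
#' @param min_overlap Minimum overlap length (default 10).
#' @param max_mismatch_density Maximum mismatch fraction in the overlap
#'   (default 0.25).
#' @return A list with `sequence`, `quality`, `overlap`,
#'   `mismatch_density`, or `NULL` on failure.
#' @export
merge_read_pair <- function(read1, read2, qual1 = NULL, qual2 = NULL,
                            min_overlap = 10, max_mismatch_density = 0.25) {
  if (nchar(read1) == 0 || nchar(read2) == 0) abort("empty read")
  qual1 <- qual1 %||% strrep("I", nchar(read1))
  qual2 <- qual2 %||% strrep("I", nchar(read2))
  r2 <- revcomp(read2)
  q2 <- paste(rev(strsplit(qual2, "")[[1]]), collapse = "")

  s1 <- strsplit(read1, "")[[1]]; s2 <- strsplit(r2, "")[[1]]
  p1 <- utf8ToInt(qual1) - 33L
  p2 <- utf8ToInt(q2) - 33L
  n1 <- length(s1); n2 <- length(s2)

  best <- NULL
  for (o in seq(min(n1, n2), min_overlap)) {
    a <- s1[(n1 - o + 1):n1]
    b <- s2[1:o]
    dens <- sum(a != b) / o
    if (dens <= max_mismatch_density &&
        (is.null(best) || dens < best$dens - 1e-12)) {
      best <- list(o = o, dens = dens) # first hit at a density wins = longest
    }
  }
  if (is.null(best)) return(NULL)

  o <- best$o
  ia <- (n1 - o + 1):n1
  qa <- p1[ia]; qb <- p2[1:o]
  a <- s1[ia]; b <- s2[1:o]
  take_a <- a == b | qa >= qb
  cons <- ifelse(take_a, a, b)
  cons_q <- pmax(qa, qb)
  seq_out <- paste0(substr(read1, 1, n1 - o), paste(cons, collapse = ""),
                    substr(r2, o + 1, n2))
  qual_out <- paste0(substr(qual1, 1, n1 - o),
                     intToUtf8(cons_q + 33L, multiple = FALSE),
                     substr(q2, o + 1, n2))
  list(sequence = seq_out, quality = qual_out, overlap = o,
       mismatch_density = best$dens)
}

#' Merge a table of read pairs
#'
#' Applies [merge_read_pair()] row-wise to paired read tables (as returned
#' by [read_fastq()]), memoizing identical sequence pairs.
#'
#' @param reads1,reads2 Tibbles with `read_id`, `sequence`, `quality`;
#'   matched by row.
#' @inheritParams merge_read_pair
#' @return A tibble with `read_id`, `sequence`, `quality`, `merged`
#'   (logical); failed merges keep `NA` sequences.
#' @export
merge_read_pairs <- function(reads1, reads2, min_overlap = 10,
                             max_mismatch_density = 0.25) {
  stopifnot(nrow(reads1) == nrow(reads2))
  cache <- new.env(parent = emptyenv())
  out_seq <- character(nrow(reads1)); out_qual <- character(nrow(reads1))
  ok <- logical(nrow(reads1))
  for (i in seq_len(nrow(reads1))) {
    key <- paste0(reads1$sequence[i], "#", reads2$sequence[i], "#",
                  reads1$quality[i], "#", reads2$quality[i])
    res <- cache[[key]]
    if (is.null(res)) {
      res <- merge_read_pair(reads1$sequence[i], reads2$sequence[i],
                             reads1$quality[i], reads2$quality[i],
                             min_overlap, max_mismatch_density)
      cache[[key]] <- if (is.null(res)) list(failed = TRUE) else res
      if (is.null(res)) res <- list(failed = TRUE)
    }
    if (!is.null(res$failed)) {
      out_seq[i] <- NA_character_; out_qual[i] <- NA_character_
    } else {
      out_seq[i] <- res$sequence; out_qual[i] <- res$quality; ok[i] <- TRUE
    }
  }
  tibble::tibble(read_id = reads1$read_id, sequence = out_seq,
                 quality = out_qual, merged = ok)
}

#' Demultiplex merged reads by barcode and isoform-specific primer
#'
#' The sample barcode is matched exactly at the 5' end of the merged read;
#' the constant-region primer that follows identifies the chain and the
#' membrane/secreted isoform and may carry at most one mismatch. Unassigned
#' reads are counted and dropped.
#'
#' @param reads Tibble with `read_id`, `sequence` (merged reads).
#' @param barcode_table Data frame with `barcode`, `sample_id`.
#' @param primer_table Data frame with `primer`, `chain`, `isoform`.
#' @return A tibble with `read_id`, `sample_id`, `chain`, `isoform`,
#'   `trimmed_sequence`; the dropped-read tally is attached as attribute
#'   `tally` and logged.
#' @export
demultiplex <- function(reads, barcode_table, primer_table) {
  barcode_table <- tibble::as_tibble(barcode_table)
  primer_table <- tibble::as_tibble(primer_table)
  if (anyDuplicated(barcode_table$barcode)) abort("colliding barcodes in table")
  if (anyDuplicated(primer_table$primer)) abort("colliding primers in table")
  reads <- reads[!is.na(reads$sequence), ]
  n <- nrow(reads)
  sample_id <- character(n); chain <- character(n); isoform <- character(n)
  trimmed <- character(n)
  no_barcode <- 0L; no_primer <- 0L
  primer_chars <- strsplit(primer_table$primer, "")
  for (i in seq_len(n)) {
    s <- reads$sequence[i]
    b_hit <- NA_integer_
    for (b in seq_len(nrow(barcode_table))) {
      bc <- barcode_table$barcode[b]
      if (substr(s, 1, nchar(bc)) == bc) { b_hit <- b; break }
    }
    if (is.na(b_hit)) { no_barcode <- no_barcode + 1L; next }
    bl <- nchar(barcode_table$barcode[b_hit])
    mm_best <- Inf; p_hit <- NA_integer_
    for (p in seq_len(nrow(primer_table))) {
      pl <- length(primer_chars[[p]])
      region <- strsplit(substr(s, bl + 1, bl + pl), "")[[1]]
      if (length(region) < pl) next
      mm <- sum(region != primer_chars[[p]])
      if (mm < mm_best) { mm_best <- mm; p_hit <- p }
    }
    if (is.na(p_hit) || mm_best > 1) { no_primer <- no_primer + 1L; next }
    sample_id[i] <- barcode_table$sample_id[b_hit]
    chain[i] <- primer_table$chain[p_hit]
    isoform[i] <- primer_table$isoform[p_hit]
    trimmed[i] <- substr(s, bl + nchar(primer_table$primer[p_hit]) + 1, nchar(s))
  }
  keep <- sample_id != ""
  out <- tibble::tibble(
    read_id = reads$read_id[keep],
    sample_id = sample_id[keep], chain = chain[keep], isoform = isoform[keep],
    trimmed_sequence = trimmed[keep]
  )
  tally <- list(assigned = sum(keep), unassigned_barcode = no_barcode,
                unassigned_primer = no_primer)
  rlang::inform(sprintf(
    "demultiplex: %d assigned, %d without barcode, %d without primer",
    tally$assigned, tally$unassigned_barcode, tally$unassigned_primer))
  attr(out, "tally") <- tally
  out
}

#' Build clonotype tables from annotated rearrangements or raw reads
#'
#' With AIRR-annotated input the clonotype key is `(v_call, j_call,
#' junction)` and counts are summed over records sharing a key within a
#' library (a `sample_id` x `chain` x `isoform` combination). With
#' demultiplexed reads (no germline annotation) the fallback key is exact
#' identity of the primer-trimmed merged sequence.
#'
#' @param records AIRR tibble (columns `v_call`, `j_call`, `junction`,
#'   `duplicate_count`, `sample_id`, `chain`, `isoform`) or a demultiplexed
#'   read tibble from [demultiplex()].
#' @param count_mode `"duplicate_count"` (weight AIRR records by their
#'   duplicate counts) or `"reads"` (count one per record/read).
#' @return A clonotype tibble with `sample_id`, `chain`, `isoform`,
#'   `v_call`, `j_call`, `junction`, `clone_key`, `count`.
#' @export
build_clonotypes <- function(records, count_mode = c("duplicate_count", "reads")) {
  count_mode <- match.arg(count_mode)
  records <- tibble::as_tibble(records)
  if ("trimmed_sequence" %in% names(records)) {
    need <- c("sample_id", "chain", "isoform", "trimmed_sequence")
    miss <- setdiff(need, names(records))
    if (length(miss) > 0) abort(paste0("missing required column(s): ",
                                       paste(miss, collapse = ", ")))
    out <- records |>
      dplyr::count(.data$sample_id, .data$chain, .data$isoform,
                   junction = .data$trimmed_sequence, name = "count") |>
      dplyr::mutate(v_call = NA_character_, j_call = NA_character_,
                    clone_key = .data$junction)
    return(dplyr::select(out, "sample_id", "chain", "isoform", "v_call",
                         "j_call", "junction", "clone_key", "count"))
  }
  need <- c("v_call", "j_call", "junction", "duplicate_count",
            "sample_id", "chain", "isoform")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- grepl("[^ACGTN]", records$junction)
  if (any(bad)) {
    abort(paste0("junction with invalid characters at row(s): ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }
  w <- if (count_mode == "duplicate_count") records$duplicate_count else 1L
  records$..w <- w
  out <- records |>
    dplyr::group_by(.data$sample_id, .data$chain, .data$isoform,
                    .data$v_call, .data$j_call, .data$junction) |>
    dplyr::summarise(count = sum(.data$..w), .groups = "drop") |>
    dplyr::mutate(clone_key = paste(.data$v_call, .data$j_call,
                                    .data$junction, sep = "|"))
  dplyr::select(out, "sample_id", "chain", "isoform", "v_call", "j_call",
                "junction", "clone_key", "count")
}

#' Top clone frequencies per library
#'
#' Per `sample_id` x `chain` x `isoform` library, clone frequencies are
#' counts over the library total; clones are sorted by descending frequency
#' (ties broken lexicographically by clone key) and the `n_top` most
#' abundant retained, the first being the dominant clone — the per-library
#' analogue of reporting the five most abundant mRNA clones.
#'
#' @param clonotypes Clonotype tibble from [build_clonotypes()].
#' @param n_top Number of top clones per library (default 5).
#' @return A tibble of class `clone_report` with `sample_id`, `chain`,
#'   `isoform`, `rank`, `clone_key`, `count`, `frequency`, `total_reads`.
#' @export
top_clone_frequencies <- function(clonotypes, n_top = 5) {
  if (n_top < 1) abort("n_top must be at least 1")
  if (nrow(clonotypes) == 0) {
    warn("empty clonotype table; empty report")
  }
  out <- clonotypes |>
    dplyr::group_by(.data$sample_id, .data$chain, .data$isoform) |>
    dplyr::mutate(total_reads = sum(.data$count),
                  frequency = .data$count / .data$total_reads) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$clone_key,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= n_top) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "chain", "isoform", "rank", "clone_key",
                  "count", "frequency", "total_reads")
  class(out) <- c("clone_report", class(out))
  out
}

#' Do the dominant membrane and secreted clones match?
#'
#' True exactly when the dominant (rank-1) clonotype keys of the membrane
#' and secreted libraries of a sample and chain are identical — the
#' signature of a clone transcribing both isoforms of the same VDJ
#' rearrangement.
#'
#' @param report A `clone_report` from [top_clone_frequencies()].
#' @param sample,chain Library identifiers.
#' @return A single logical.
#' @export
dominant_isoform_match <- function(report, sample, chain) {
  dom <- report[report$sample_id == sample & report$chain == chain &
                  report$rank == 1, ]
  for (iso in c("membrane", "secreted")) {
    if (!iso %in% dom$isoform) {
      abort(paste0("missing ", iso, " library for ", sample, " / ", chain))
    }
  }
  dom$clone_key[dom$isoform == "membrane"] ==
    dom$clone_key[dom$isoform == "secreted"]
}

#' @rdname dominant_isoform_match
#' @description `dominant_matches()` tabulates the flag for every
#'   sample x chain with both isoform libraries present.
#' @return `dominant_matches()` returns a tibble with `sample_id`, `chain`,
#'   `membrane_key`, `secreted_key`, `dominant_match`.
#' @export
dominant_matches <- function(report) {
  dom <- report[report$rank == 1, ] |>
    dplyr::select("sample_id", "chain", "isoform", "clone_key") |>
    tidyr::pivot_wider(names_from = "isoform", values_from = "clone_key")
  if (!all(c("membrane", "secreted") %in% names(dom))) {
    abort("report lacks membrane or secreted libraries")
  }
  dom |>
    dplyr::filter(!is.na(.data$membrane), !is.na(.data$secreted)) |>
    dplyr::transmute(.data$sample_id, .data$chain,
                     membrane_key = .data$membrane,
                     secreted_key = .data$secreted,
                     dominant_match = .data$membrane == .data$secreted)
}

#' Exact Wilcoxon rank-sum test by enumeration
#'
#' For small samples (`n + m <= 12`) the p-value is exact: all
#' `choose(n + m, n)` assignments of the pooled mid-ranks to the first
#' group are enumerated and the rank-sum statistic's tail probabilities
#' computed directly, so ties are handled exactly. The two-sided p-value is
#' `min(1, 2 * min(tail probabilities))`. Larger samples fall back to the
#' normal approximation with tie correction and continuity correction
#' (logged).
#'
#' @param x,y Numeric vectors (non-empty).
#' @param alternative `"two.sided"`, `"less"` (x tends smaller) or
#'   `"greater"`.
#' @return A list of class `htest` with `statistic` (rank sum of `x`) and
#'   `p.value`.
#' @export
ranksum_exact <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) abort("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)])
  eps <- 1e-9
  if (n + m <= 12) {
    sums <- combn(n + m, n, function(idx) sum(r[idx]))
    p_le <- mean(sums <= w + eps)
    p_ge <- mean(sums >= w - eps)
    method <- "Exact Wilcoxon rank-sum test (full enumeration)"
  } else {
    rlang::inform("ranksum_exact: n + m > 12, using normal approximation")
    N <- n + m
    mu <- n * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    sigma <- sqrt(sigma2)
    p_le <- stats::pnorm((w - mu + 0.5) / sigma)
    p_ge <- stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  p <- switch(alternative,
    two.sided = min(1, 2 * min(p_le, p_ge)),
    less = p_le,
    greater = p_ge
  )
  structure(
    list(statistic = c(W = w), p.value = p, alternative = alternative,
         method = method, data.name = "x and y"),
    class = "htest"
  )
}
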