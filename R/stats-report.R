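## Assembly summary statistics (N50 and friends), histogram tables, and the
## consolidated multi-stage pipeline runner.

#' N50 of a length multiset
#'
#' The largest length L such that sequences of length at least L together
#' contain at least half of the total bases (the standard contig N50).
#'
#' @param lengths integer vector of sequence lengths.
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0)
  lens <- sort(lengths, decreasing = TRUE)
  lens[which(cumsum(as.numeric(lens)) >= sum(as.numeric(lens)) / 2)[1]]
}

#' Assembly summary statistics
#'
#' Sequences shorter than `length_floor` are excluded (and counted in
#' `n_below_floor`); the mean length is rounded half-up to an integer, as in
#' conventional assembly summary tables.
#'
#' @param transcripts named character vector of sequences, a FASTA path, or an
#'   integer vector of lengths.
#' @param length_floor minimum length included (default 100 bp).
#' @return an `assembly_stats` list: `n_transcripts`, `n50`, `mean_len`,
#'   `min_len`, `max_len`, `total_bases`, `n_over_1kb`, `n_below_floor`.
#' @export
assembly_stats <- function(transcripts, length_floor = 100L) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      is.null(names(transcripts)) && file.exists(transcripts))
    transcripts <- read_fasta(transcripts)
  lens <- if (is.numeric(transcripts)) as.integer(transcripts)
          else nchar(transcripts)
  n_below <- sum(lens < length_floor)
  lens <- lens[lens >= length_floor]
  if (!length(lens))
    stop("assembly_stats: no sequences at or above the length floor")
  structure(list(
    n_transcripts = length(lens),
    n50 = n50(lens),
    mean_len = as.integer(round_half_up(mean(lens))),
    min_len = min(lens),
    max_len = max(lens),
    total_bases = sum(as.numeric(lens)),
    n_over_1kb = sum(lens > 1000L),
    n_below_floor = n_below
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("assembly_stats: %d transcripts, N50 %d, mean %d bp,",
                     " range %d-%d bp, %s bases, %d > 1 kb\n"),
              x$n_transcripts, x$n50, x$mean_len, x$min_len, x$max_len,
              format(x$total_bases, big.mark = ","), x$n_over_1kb))
  invisible(x)
}

#' Histogram counts with left-closed, right-open bins
#'
#' Values falling at an internal edge go to the right bin; values at or above
#' the last edge are collected in an overflow bin, so counts always conserve
#' the number of input values.
#'
#' @param values numeric vector.
#' @param bin_edges strictly increasing numeric vector of edges.
#' @return data.frame with `bin_start`, `bin_end` (NA for the overflow bin)
#'   and `count`.
#' @export
histogram_counts <- function(values, bin_edges) {
  if (any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing")
  k <- length(bin_edges)
  counts <- integer(k)      # k-1 interior bins + overflow; underflow dropped
  if (length(values)) {
    idx <- findInterval(values, bin_edges)
    if (any(idx == 0L))
      stop("histogram_counts: values below the first bin edge")
    counts <- tabulate(idx, nbins = k)
  }
  data.frame(bin_start = bin_edges,
             bin_end = c(bin_edges[-1], NA),
             count = counts)
}

#' Run the post-assembly pipeline on a set of input files
#'
#' Orchestrates the stages in their natural order: read trimming, per-locus
#' representative selection per k-assembly, additive multiple-k merging,
#' coverage/rRNA filtering, microsatellite scanning and summary statistics.
#' Stages run only when their inputs are present in `config`, so e.g. a
#' statistics-only run on a single FASTA is valid.
#'
#' @param config list with any of: `fastq_mate1`, `fastq_mate2` (paths),
#'   `k_fasta` (named list k -> FASTA path), `sam` (alignment path, enables
#'   the coverage stage), `rrna_ids` (character), `min_len`, `phred_min`,
#'   `identity_threshold`, `mean_min`, `gap_fraction`, `end_margin`,
#'   `length_floor`, `msat_min_units`, `final_fasta` (stats-only input),
#'   `out_dir` (where stage outputs are written; default a temp directory).
#' @return a `pipeline_result` list with per-stage outputs (`trimmed`,
#'   `representatives`, `merged`, `filtered`, `msat`, `stats`) and `report`, a
#'   data.frame of per-stage transcript counts in the shape of an assembly
#'   summary table (per-k Initial/Representative rows, then Merged and Final).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% tempfile("pipeline")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  report <- list()
  floor <- config$length_floor %||% 100L

  if (!is.null(config$fastq_mate1)) {
    if (is.null(config$fastq_mate2))
      stop("configuration error: fastq_mate1 given without fastq_mate2")
    m1 <- read_fastq(config$fastq_mate1)
    m2 <- read_fastq(config$fastq_mate2)
    res$trimmed <- filter_and_sort(m1, m2,
                                   min_len = config$min_len %||% 25L,
                                   phred_min = config$phred_min %||% 13L)
    write_fastq(res$trimmed$paired$mate1, file.path(out_dir, "trimmed_1.fastq"))
    write_fastq(res$trimmed$paired$mate2, file.path(out_dir, "trimmed_2.fastq"))
    write_fastq(res$trimmed$singletons,
                file.path(out_dir, "trimmed_singletons.fastq"))
  }

  merged <- NULL
  if (!is.null(config$k_fasta)) {
    reps <- list()
    for (k in names(config$k_fasta)) {
      asm <- read_kmer_assembly(config$k_fasta[[k]], as.integer(k),
                                min_len = floor)
      rep_k <- select_representatives(asm)
      st_i <- if (nrow(asm)) assembly_stats(nchar(asm$sequence), floor) else NULL
      st_r <- if (nrow(rep_k)) assembly_stats(nchar(rep_k$sequence), floor) else NULL
      report[[length(report) + 1L]] <- data.frame(
        kmer = k, stage = "Initial", n = nrow(asm),
        n50 = if (is.null(st_i)) NA else st_i$n50,
        mean_len = if (is.null(st_i)) NA else st_i$mean_len)
      report[[length(report) + 1L]] <- data.frame(
        kmer = k, stage = "Representative", n = nrow(rep_k),
        n50 = if (is.null(st_r)) NA else st_r$n50,
        mean_len = if (is.null(st_r)) NA else st_r$mean_len)
      reps[[k]] <- rep_k
    }
    res$representatives <- do.call(rbind, reps)
    merged <- cluster_and_merge(
      res$representatives,
      identity_threshold = config$identity_threshold %||% 0.95)
    res$merged <- merged
    write_merged_set(merged, file.path(out_dir, "merged.fasta"),
                     file.path(out_dir, "clusters.tsv"))
    stm <- assembly_stats(nchar(merged$transcripts$sequence), floor)
    report[[length(report) + 1L]] <- data.frame(
      kmer = "", stage = "Merged", n = stm$n_transcripts, n50 = stm$n50,
      mean_len = stm$mean_len)
  }

  final_seqs <- if (!is.null(merged))
    setNames(merged$transcripts$sequence, merged$transcripts$id)
  else if (!is.null(config$final_fasta)) read_fasta(config$final_fasta)
  else NULL

  if (!is.null(config$sam) && !is.null(final_seqs)) {
    profiles <- depth_from_alignments(config$sam, final_seqs)
    res$filtered <- apply_filters(
      profiles, rrna_ids = config$rrna_ids %||% character(),
      mean_min = config$mean_min %||% 3,
      gap_fraction = config$gap_fraction %||% 0.1,
      end_margin = config$end_margin %||% 0L)
    final_seqs <- final_seqs[res$filtered$kept_ids]
    write_fasta(final_seqs, file.path(out_dir, "final.fasta"))
    write.table(res$filtered$decisions, file.path(out_dir, "decisions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(final_seqs)) {
    names(final_seqs) <- sub("\\s.*$", "", names(final_seqs))
    res$msat <- scan_microsatellites(
      final_seqs,
      min_units = config$msat_min_units %||% c(`2` = 10L, `3` = 7L, `4` = 5L))
    res$stats <- assembly_stats(final_seqs, floor)
    report[[length(report) + 1L]] <- data.frame(
      kmer = "", stage = "Final", n = res$stats$n_transcripts,
      n50 = res$stats$n50, mean_len = res$stats$mean_len)
  }

  res$report <- if (length(report)) do.call(rbind, report) else
    data.frame(kmer = character(), stage = character(), n = integer(),
               n50 = integer(), mean_len = integer())
  res$out_dir <- out_dir
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
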