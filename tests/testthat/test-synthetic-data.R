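test_that("configuration validation names the offending field", {
  expect_error(simulation_config(n_loci = 0), "n_loci")
  expect_error(simulation_config(length_range = c(50, 200)), "length_range")
  expect_error(simulation_config(kmer_list = c(21, 21)), "kmer_list")
  expect_error(simulation_config(kmer_list = c(20, 24)), "kmer_list")
  expect_error(simulation_config(capture_prob_per_k = 1.2), "capture_prob_per_k")
  expect_error(simulation_config(truncation_frac_range = c(0, 1)),
               "truncation_frac_range")
  expect_error(simulation_config(chimera_rate = -0.1), "chimera_rate")
  expect_error(simulation_config(msat_plant = list(list(motif = "ACGTA",
                                                        units = 5))),
               "msat_plant")
})

test_that("truth generation is deterministic and conserves expression weight", {
  cfg <- small_config(n_loci = 50L, seed = 7L)
  b1 <- generate_truth_transcriptome(cfg)
  b2 <- generate_truth_transcriptome(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_equal(nrow(b1$truth), 50L)
  expect_equal(sum(b1$truth$expression_weight), 1, tolerance = 1e-12)
  expect_true(all(grepl("^[ACGT]+$", b1$truth$sequence)))

  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(setNames(b1$truth$sequence, b1$truth$id), f1)
  write_fasta(setNames(b2$truth$sequence, b2$truth$id), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted microsatellites are present verbatim at recorded coordinates", {
  cfg <- small_config(msat_plant = list(list(motif = "AC", units = 12),
                                        list(motif = "ACGT", units = 6)))
  b <- generate_truth_transcriptome(cfg)
  expect_equal(nrow(b$msat_loci), 2L)
  for (i in seq_len(nrow(b$msat_loci))) {
    m <- b$msat_loci[i, ]
    seq <- b$truth$sequence[b$truth$id == m$transcript_id]
    expect_identical(substr(seq, m$start, m$end),
                     strrep(m$motif, m$unit_count))
  }
})

test_that("degenerate length range gives constant transcript lengths", {
  cfg <- small_config(length_range = c(200L, 200L))
  b <- generate_truth_transcriptome(cfg)
  expect_true(all(b$truth$length == 200L))
})

test_that("full capture without truncation or chimeras reproduces every locus in every k", {
  cfg <- small_config(n_loci = 15L, capture_prob_per_k = 1,
                      truncation_frac_range = c(1, 1), chimera_rate = 0)
  b <- simulate_multik_assemblies(generate_truth_transcriptome(cfg))
  for (k in cfg$kmer_list) {
    rows <- b$assembly[b$assembly$kmer == k, ]
    expect_setequal(unique(rows$truth_locus), b$truth$id)
    expect_true(all(rows$sequence ==
                    b$truth$sequence[match(rows$truth_locus, b$truth$id)]))
  }
  expect_length(b$chimera_ids, 0L)
})

test_that("emitted fusion count equals the recorded chimera ids and parents map to two loci", {
  cfg <- small_config(n_loci = 50L, chimera_rate = 0.1, seed = 5L)
  b <- simulate_multik_assemblies(generate_truth_transcriptome(cfg))
  n_fusions_in_fasta <- sum(b$assembly$is_chimera)
  expect_equal(n_fusions_in_fasta, length(b$chimera_ids))
  expect_gt(n_fusions_in_fasta, 0L)
  for (id in b$chimera_ids) {
    expect_length(b$truth_locus_of[[id]], 2L)
    row <- b$assembly[b$assembly$id == id, ]
    pA <- b$truth$sequence[b$truth$id == row$truth_locus]
    pB <- b$truth$sequence[b$truth$id == row$truth_locus2]
    expect_identical(row$sequence,
                     paste0(substr(pA, 1, row$junction),
                            substr(pB, row$src_start2, nchar(pB))))
  }
  ## non-chimeric transcripts map to exactly one truth locus
  normal <- setdiff(b$assembly$id, b$chimera_ids)
  expect_true(all(lengths(b$truth_locus_of[normal]) == 1L))
})

test_that("emitted headers parse back consistently with sequence lengths", {
  cfg <- small_config(n_loci = 10L)
  b <- simulate_multik_assemblies(generate_truth_transcriptome(cfg))
  seqs <- read_fasta(b$k_assembly_files[[1]])
  for (i in seq_along(seqs)) {
    meta <- parse_oases_header(names(seqs)[i])
    expect_equal(meta$declared_length, nchar(seqs[[i]]))
    expect_lte(meta$transcript_index, meta$isoform_count)
  }
})

test_that("read simulation is deterministic, honours weights, and matches its quality model", {
  cfg <- small_config(n_loci = 5L, n_read_pairs = 500L, seed = 9L)
  b1 <- simulate_reads(generate_truth_transcriptome(cfg))
  b2 <- simulate_reads(generate_truth_transcriptome(cfg))
  expect_identical(readLines(b1$fastq$mate1), readLines(b2$fastq$mate1))
  expect_identical(readLines(b1$fastq$mate2), readLines(b2$fastq$mate2))

  ## degenerate weights: all reads from the dominant locus
  cfg2 <- small_config(n_loci = 10L, n_read_pairs = 200L,
                       expression_shape = 60)
  b <- generate_truth_transcriptome(cfg2)
  top <- b$truth$id[which.max(b$truth$expression_weight)]
  b <- simulate_reads(b)
  expect_true(all(b$read_origins$locus == top))

  ## zero pairs: empty but valid FASTQ
  b0 <- simulate_reads(generate_truth_transcriptome(
    small_config(n_read_pairs = 0L)))
  expect_length(read_fastq(b0$fastq$mate1), 0L)
})

test_that("a clean Q40 profile yields ~1e-4 per-read error and 100% Q20", {
  cfg <- small_config(
    n_loci = 3L, n_read_pairs = 400L,
    quality_profile = list(q_start = 40, q_slope = 0, q_sd = 0, n_rate = 0,
                           p_degraded = 0))
  b <- simulate_reads(generate_truth_transcriptome(cfg))
  reads <- read_fastq(b$fastq$mate1)
  expect_true(all(unlist(reads$qual) == 40L))
  s <- read_set_summary(reads)
  expect_equal(s$q20_pct, 100)
  ## realised mismatch rate vs the truth should sit near 1e-4
  raw <- substr(b$truth$sequence[match(b$read_origins$locus, b$truth$id)],
                b$read_origins$start, b$read_origins$start + cfg$read_length - 1)
  obs <- mapply(function(a, b_) sum(strsplit(a, "")[[1]] != strsplit(b_, "")[[1]]),
                reads$seq, raw)
  rate <- sum(obs) / (length(reads) * cfg$read_length)
  expect_lt(rate, 5e-4)
})

test_that("realised sequencing depth matches the configured target", {
  ## single 1000 bp locus, depth target 20 => 200 pairs of 2x50 bp
  deviations <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_loci = 1L, length_range = c(1000L, 1000L),
                             n_read_pairs = 200L, chimera_rate = 0,
                             capture_prob_per_k = 1,
                             truncation_frac_range = c(1, 1), seed = s)
    b <- simulate_reads(simulate_multik_assemblies(
      generate_truth_transcriptome(cfg)))
    sam <- tempfile(fileext = ".sam")
    id <- b$assembly$id[b$assembly$kmer == 21][1]
    simulate_alignments(b, id, sam)
    prof <- depth_from_alignments(sam, setNames(
      b$assembly$sequence[b$assembly$id == id], id))
    prof[[1]]$mean_depth
  }, numeric(1))
  ## interior target 20 minus edge ramp-down; use generous sampling bounds
  expect_gt(mean(deviations), 20 * 0.85)
  expect_lt(mean(deviations), 20 * 1.05)
})

test_that("the truth manifest records every planted feature", {
  cfg <- small_config(msat_plant = list(list(motif = "AT", units = 11)),
                      rrna_frac = 0.1, chimera_rate = 0.1)
  b <- simulate_multik_assemblies(generate_truth_transcriptome(cfg))
  path <- tempfile(fileext = ".tsv")
  write_truth_manifest(b, path)
  man <- read.delim(path, stringsAsFactors = FALSE)
  expect_setequal(man$id[man$type == "truth"], b$truth$id)
  expect_setequal(man$id[man$type == "chimera"], b$chimera_ids)
  expect_setequal(man$id[man$type == "rrna"], b$rrna_ids)
  expect_equal(sum(man$type == "msat"), nrow(b$msat_loci))
})
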