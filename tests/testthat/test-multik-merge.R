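test_that("Oases-style headers parse and malformed headers are rejected", {
  m <- parse_oases_header("Locus_4_Transcript_2/3_Confidence_0.429_Length_812")
  expect_equal(m$locus_id, "4")
  expect_equal(m$transcript_index, 2L)
  expect_equal(m$isoform_count, 3L)
  expect_equal(m$confidence, 0.429)
  expect_equal(m$declared_length, 812L)

  m <- parse_oases_header("Locus_1_Transcript_1/1_Confidence_1.000_Length_100")
  expect_equal(m$isoform_count, 1L)

  expect_error(parse_oases_header("Contig_17"), "Contig_17")
  expect_error(parse_oases_header("Locus_1_Transcript_3/2_Confidence_1.0_Length_5"),
               "isoform count")
})

test_that("assembly loading checks declared lengths and applies the 100 bp floor", {
  path <- tempfile(fileext = ".fasta")
  write_fasta(c("Locus_1_Transcript_1/1_Confidence_0.500_Length_120" =
                  random_seq(120),
                "Locus_2_Transcript_1/1_Confidence_0.500_Length_80" =
                  random_seq(80)), path)
  asm <- read_kmer_assembly(path, 21)
  expect_equal(nrow(asm), 1L)   # 80 bp transcript dropped at load
  expect_equal(asm$id, "21_Locus_1_Transcript_1")

  write_fasta(c("Locus_1_Transcript_1/1_Confidence_0.500_Length_130" =
                  random_seq(120)), path)
  expect_error(read_kmer_assembly(path, 21), "length mismatch")
})

test_that("representative selection prefers length, then confidence, then index", {
  asm <- data.frame(
    kmer = 21L, locus_id = c("1", "1", "2", "3", "3", "3"),
    transcript_index = c(1L, 2L, 1L, 3L, 1L, 2L),
    isoform_count = c(2L, 2L, 1L, 3L, 3L, 3L),
    confidence = c(0.4, 0.9, 0.5, 0.4, 0.9, 0.9),
    sequence = c(random_seq(800), random_seq(600),   # locus 1: length wins
                 random_seq(300),                    # locus 2: singleton
                 random_seq(500), random_seq(500), random_seq(500)),
    stringsAsFactors = FALSE)
  asm$declared_length <- nchar(asm$sequence)
  asm$id <- sprintf("21_Locus_%s_Transcript_%d", asm$locus_id,
                    asm$transcript_index)
  reps <- select_representatives(asm)
  expect_equal(nrow(reps), 3L)
  expect_equal(nchar(reps$sequence[reps$locus_id == "1"]), 800L)
  expect_equal(reps$transcript_index[reps$locus_id == "2"], 1L)
  ## locus 3: equal lengths, confidence 0.9 beats 0.4, index 1 beats index 2
  expect_equal(reps$confidence[reps$locus_id == "3"], 0.9)
  expect_equal(reps$transcript_index[reps$locus_id == "3"], 1L)
})

test_that("pairwise identity matches closed-form values and the DP score oracle", {
  a <- random_seq(100)
  expect_equal(pairwise_identity(a, a), 1)

  ## 5 substitutions in 100 bp
  set.seed(3)
  b <- mutate_subs(a, 5)
  expect_equal(pairwise_identity(a, b), 0.95)

  ## disjoint alphabets share no aligned identical base
  expect_equal(pairwise_identity(strrep("A", 50), strrep("C", 50)), 0)

  ## an exact substring has identity 1 under the shorter-sequence denominator
  expect_equal(pairwise_identity(substr(a, 20, 79), a), 1)

  expect_error(pairwise_identity("", "ACGT"), "empty")

  ## alignment scores agree with an independent affine-gap DP on fuzzed pairs
  set.seed(4)
  for (i in 1:60) {
    p <- random_seq(sample(5:25, 1))
    s <- random_seq(sample(5:40, 1))
    pa <- Biostrings::pairwiseAlignment(
      p, s, type = if (nchar(p) <= nchar(s)) "global-local" else "local-global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
      gapOpening = 1, gapExtension = 1)
    expect_equal(Biostrings::score(pa), oracle_semiglobal_score(p, s))
  }
})

test_that("greedy merge collapses fragments into parents and keeps unrelated apart", {
  parent <- random_seq(1000)
  frag <- substr(parent, 201, 800)
  other <- random_seq(500)
  reps <- data.frame(id = c("k21_p", "k33_frag", "k25_other"),
                     kmer = c(21L, 33L, 25L),
                     sequence = c(parent, frag, other),
                     stringsAsFactors = FALSE)
  m <- cluster_and_merge(reps)
  expect_equal(sort(m$transcripts$id), c("k21_p", "k25_other"))
  expect_equal(m$clusters$representative_id[m$clusters$member_id == "k33_frag"],
               "k21_p")
  expect_equal(m$clusters$identity[m$clusters$member_id == "k33_frag"], 1)
  expect_error(cluster_and_merge(reps, identity_threshold = 1.5),
               "identity_threshold")
})

test_that("merged output is non-redundant, representative-dominant and idempotent", {
  set.seed(5)
  parents <- vapply(sample(300:900, 6), random_seq, character(1))
  seqs <- c(parents,
            vapply(parents[1:4], function(p)
              substr(p, 50, nchar(p) - 30), character(1)),
            vapply(parents[1:3], function(p) mutate_subs(p, 3), character(1)))
  reps <- data.frame(id = sprintf("s%02d", seq_along(seqs)), kmer = 21L,
                     sequence = unname(seqs), stringsAsFactors = FALSE)
  m <- cluster_and_merge(reps)
  out <- m$transcripts$sequence
  ## all output pairs below the threshold
  for (i in seq_along(out)) for (j in seq_len(i - 1L))
    expect_lt(pairwise_identity(out[i], out[j]), 0.95)
  ## representative is at least as long as every member
  rep_len <- setNames(nchar(m$transcripts$sequence), m$transcripts$id)
  mem_len <- setNames(nchar(reps$sequence), reps$id)
  expect_true(all(rep_len[m$clusters$representative_id] >=
                  mem_len[m$clusters$member_id]))
  ## adding an exact duplicate of an output transcript changes nothing
  again <- rbind(m$transcripts[, c("id", "kmer", "sequence")],
                 data.frame(id = "dup", kmer = 41L,
                            sequence = out[1], stringsAsFactors = FALSE))
  m2 <- cluster_and_merge(again)
  expect_setequal(m2$transcripts$sequence, out)
})

test_that("cluster assignments agree with the brute-force greedy oracle", {
  set.seed(6)
  for (rep_i in 1:3) {
    parents <- vapply(sample(150:500, 8), random_seq, character(1))
    seqs <- c(parents,
              vapply(sample(parents, 12, replace = TRUE), function(p) {
                L <- nchar(p)
                s <- sample.int(L %/% 3, 1)
                substr(mutate_subs(p, sample(0:3, 1)), s, s + sample((L %/% 2):(L - s), 1))
              }, character(1)),
              vapply(sample(100:300, 5), random_seq, character(1)))
    names(seqs) <- NULL
    df <- data.frame(id = sprintf("q%02d", seq_along(seqs)), kmer = 21L,
                     sequence = seqs, stringsAsFactors = FALSE)
    m <- cluster_and_merge(df)
    oracle <- oracle_greedy_clusters(seqs)
    ## same partition: members grouped with the same representative sequence
    got <- split(m$clusters$member_id, m$clusters$representative_id)
    want <- split(df$id, oracle)
    normalise <- function(g) unname(lapply(g[order(vapply(g, min, ""))], sort))
    expect_identical(normalise(got), normalise(want))
  }
})

test_that("merging a full-capture untruncated bundle recovers the locus count", {
  cfg <- small_config(n_loci = 12L, capture_prob_per_k = 1,
                      truncation_frac_range = c(1, 1), chimera_rate = 0)
  b <- simulate_multik_assemblies(generate_truth_transcriptome(cfg))
  reps <- do.call(rbind, lapply(names(b$k_assembly_files), function(k)
    select_representatives(read_kmer_assembly(b$k_assembly_files[[k]],
                                              as.integer(k)))))
  m <- cluster_and_merge(reps)
  expect_equal(nrow(m$transcripts), cfg$n_loci)
})
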