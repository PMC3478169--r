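## Synthetic-data generator: ground-truth transcriptomes, multi-k
## pseudo-assemblies, paired short reads and planted defects (chimeras,
## microsatellites, rRNA tags), so every downstream stage of the pipeline has
## a self-contained test surface.

#' Build and validate a simulation configuration
#'
#' The configuration describes a small de novo transcriptome study: a set of
#' truth transcripts with long-tailed expression, six overlapping k-mer
#' assemblies containing truncated/duplicated copies of the truth loci, paired
#' 50 bp reads with a decaying per-cycle quality profile, and planted defects
#' (chimeric fusions, microsatellites, rRNA-tagged loci).
#'
#' @param n_loci number of ground-truth transcripts.
#' @param length_range integer pair, transcript length bounds in bp
#'   (minimum at least 100).
#' @param expression_shape exponent of the discretised power-law expression
#'   distribution (weight of rank r proportional to `r^-expression_shape`);
#'   larger values concentrate reads on fewer loci.
#' @param kmer_list strictly increasing odd k-mer sizes, one pseudo-assembly
#'   per value.
#' @param capture_prob_per_k probability that a truth locus is represented in
#'   any given k-assembly.
#' @param truncation_frac_range range of the fraction of truth length retained
#'   by a k-assembly copy (contiguous substring, uniform anchor).
#' @param n_read_pairs number of simulated read pairs.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment (insert) length distribution, bp.
#' @param quality_profile list with per-cycle mean Phred at cycle one
#'   (`q_start`), linear decay per cycle (`q_slope`), per-base Gaussian jitter
#'   (`q_sd`), the probability a base is masked to N (`n_rate`), and a
#'   degraded-tail component: a fraction `p_degraded` of reads collapse to
#'   mean Phred `q_degraded` from a uniformly drawn onset cycle, emulating the
#'   per-read quality failures that make quality trimming consequential.
#' @param chimera_rate fraction of emitted k-assembly transcripts that are
#'   fusions of two truth loci.
#' @param msat_plant list of planted microsatellites; each element a list (or
#'   2-vector) with `motif` (2-4 bp) and `units` (repeat count).
#' @param rrna_frac fraction of truth loci tagged as ribosomal.
#' @param seed integer master seed; identical config + seed gives
#'   byte-identical outputs.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_loci = 60L,
                              length_range = c(100L, 5750L),
                              expression_shape = 1.0,
                              kmer_list = c(21L, 25L, 29L, 33L, 37L, 41L),
                              capture_prob_per_k = 0.6,
                              truncation_frac_range = c(0.5, 1),
                              n_read_pairs = 20000L,
                              read_length = 50L,
                              insert_mean = 200,
                              insert_sd = 30,
                              quality_profile = list(q_start = 36, q_slope = -0.28,
                                                     q_sd = 3, n_rate = 0.001,
                                                     p_degraded = 0.15,
                                                     q_degraded = 6),
                              chimera_rate = 0.05,
                              msat_plant = list(),
                              rrna_frac = 0.02,
                              seed = 1L) {
  cfg_fail <- function(field, why) {
    stop(sprintf("invalid configuration field '%s': %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1)
    cfg_fail("n_loci", "must be a positive integer")
  if (length(length_range) != 2L || any(length_range < 100) ||
      length_range[1] > length_range[2])
    cfg_fail("length_range", "must be an increasing pair with minimum >= 100")
  if (!is.numeric(expression_shape) || expression_shape <= 0)
    cfg_fail("expression_shape", "must be positive")
  if (length(kmer_list) < 1L || any(diff(kmer_list) <= 0) ||
      any(kmer_list %% 2 == 0))
    cfg_fail("kmer_list", "must be strictly increasing odd integers")
  if (capture_prob_per_k < 0 || capture_prob_per_k > 1)
    cfg_fail("capture_prob_per_k", "must be in [0, 1]")
  if (length(truncation_frac_range) != 2L ||
      any(truncation_frac_range <= 0) || any(truncation_frac_range > 1) ||
      truncation_frac_range[1] > truncation_frac_range[2])
    cfg_fail("truncation_frac_range", "must be an increasing pair in (0, 1]")
  if (!is.numeric(n_read_pairs) || n_read_pairs < 0)
    cfg_fail("n_read_pairs", "must be a non-negative integer")
  if (!is.numeric(read_length) || read_length < 1)
    cfg_fail("read_length", "must be a positive integer")
  if (chimera_rate < 0 || chimera_rate > 1)
    cfg_fail("chimera_rate", "must be in [0, 1]")
  if (rrna_frac < 0 || rrna_frac > 1)
    cfg_fail("rrna_frac", "must be in [0, 1]")
  for (nm in c("q_start", "q_slope", "q_sd", "n_rate"))
    if (is.null(quality_profile[[nm]]))
      cfg_fail("quality_profile", sprintf("missing component '%s'", nm))
  quality_profile$p_degraded <- quality_profile$p_degraded %||% 0
  quality_profile$q_degraded <- quality_profile$q_degraded %||% 6
  msat_plant <- lapply(msat_plant, function(m) {
    m <- as.list(m)
    if (is.null(names(m)) || !all(c("motif", "units") %in% names(m)))
      m <- list(motif = as.character(m[[1]]), units = as.integer(m[[2]]))
    m$motif <- toupper(as.character(m$motif))
    m$units <- as.integer(m$units)
    if (!nchar(m$motif) %in% 2:4 || !grepl("^[ACGT]+$", m$motif))
      cfg_fail("msat_plant", "motif must be 2-4 bp over ACGT")
    if (m$units < 2L) cfg_fail("msat_plant", "units must be >= 2")
    m
  })
  structure(list(
    n_loci = as.integer(n_loci), length_range = as.integer(length_range),
    expression_shape = expression_shape, kmer_list = as.integer(kmer_list),
    capture_prob_per_k = capture_prob_per_k,
    truncation_frac_range = truncation_frac_range,
    n_read_pairs = as.integer(n_read_pairs),
    read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    quality_profile = quality_profile, chimera_rate = chimera_rate,
    msat_plant = msat_plant, rrna_frac = rrna_frac, seed = as.integer(seed)
  ), class = "simulation_config")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## plant motif x units at a random interior position; flanking bases are
## forced off the repeat's periodic continuation so the run is maximal and the
## scanner recovers the exact recorded coordinates
plant_msat <- function(seq, motif, units) {
  k <- nchar(motif)
  run <- strrep(motif, units)
  L <- nchar(seq)
  w <- nchar(run)
  if (L < w + 2L) return(NULL)
  start <- sample.int(L - w - 1L, 1L) + 1L   # keep >=1 bp flank each side
  end <- start + w - 1L
  left_block <- sample(setdiff(DNA_BASES, substr(motif, k, k)), 1L)
  right_block <- sample(setdiff(DNA_BASES, substr(motif, 1L, 1L)), 1L)
  seq <- paste0(substr(seq, 1L, start - 2L), left_block, run, right_block,
                substr(seq, end + 2L, L))
  list(seq = seq, start = start, end = end)
}

#' Generate a ground-truth transcriptome
#'
#' Draws `n_loci` random transcripts with log-normal lengths clipped to
#' `length_range`, assigns power-law expression weights (normalised to sum to
#' one), plants the requested microsatellites verbatim at recorded
#' coordinates, and tags a fraction of loci as ribosomal.
#'
#' @param config a [simulation_config()].
#' @return a `truth_bundle` list with elements `truth` (data.frame: `id`,
#'   `sequence`, `length`, `expression_weight`), `msat_loci` (data.frame:
#'   `transcript_id`, `motif`, `start`, `end`, `unit_count`), `rrna_ids`,
#'   `chimera_ids` (empty until assemblies are simulated) and `config`.
#' @export
generate_truth_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "truth"))
  n <- config$n_loci
  lo <- config$length_range[1]; hi <- config$length_range[2]
  lens <- round(rlnorm(n, meanlog = log(450), sdlog = 0.85))
  lens <- pmin(pmax(lens, lo), hi)
  ids <- sprintf("tx%04d", seq_len(n))
  seqs <- vapply(lens, random_dna, character(1))

  ## expression: power-law over a random rank permutation
  ranks <- sample.int(n)
  w <- ranks^(-config$expression_shape)
  w <- w / sum(w)

  msat <- list()
  if (length(config$msat_plant)) {
    hosts <- sample.int(n, length(config$msat_plant), replace = TRUE)
    for (i in seq_along(config$msat_plant)) {
      m <- config$msat_plant[[i]]
      ## hosts must be long enough to take the run plus broken flanks
      need <- nchar(m$motif) * m$units + 4L
      h <- hosts[i]
      if (lens[h] < need) h <- which.max(lens)
      pl <- plant_msat(seqs[h], m$motif, m$units)
      if (is.null(pl)) next
      seqs[h] <- pl$seq
      msat[[length(msat) + 1L]] <- data.frame(
        transcript_id = ids[h], motif = m$motif, start = pl$start,
        end = pl$end, unit_count = m$units, stringsAsFactors = FALSE)
    }
  }
  msat_loci <- if (length(msat)) do.call(rbind, msat) else
    data.frame(transcript_id = character(), motif = character(),
               start = integer(), end = integer(), unit_count = integer(),
               stringsAsFactors = FALSE)

  n_rrna <- floor(config$rrna_frac * n)
  rrna_ids <- if (n_rrna > 0) sort(sample(ids, n_rrna)) else character()

  structure(list(
    truth = data.frame(id = ids, sequence = seqs, length = nchar(seqs),
                       expression_weight = w, stringsAsFactors = FALSE),
    msat_loci = msat_loci, rrna_ids = rrna_ids, chimera_ids = character(),
    config = config
  ), class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("truth_bundle: %d loci (%d-%d bp), %d planted msat, %d rRNA-tagged\n",
              nrow(x$truth), min(x$truth$length), max(x$truth$length),
              nrow(x$msat_loci), length(x$rrna_ids)))
  if (!is.null(x$assembly))
    cat(sprintf("  k-assemblies: %s (%d transcripts, %d chimeric)\n",
                paste(x$config$kmer_list, collapse = ","), nrow(x$assembly),
                length(x$chimera_ids)))
  if (!is.null(x$read_origins))
    cat(sprintf("  reads: %d pairs of %d bp\n", nrow(x$read_origins),
                x$config$read_length))
  invisible(x)
}

oases_header <- function(locus, index, m, conf, len) {
  sprintf("Locus_%d_Transcript_%d/%d_Confidence_%.3f_Length_%d",
          locus, index, m, conf, len)
}

#' Simulate multiple-k pseudo-assemblies from a truth bundle
#'
#' For each k in the configuration each truth locus is captured with
#' probability `capture_prob_per_k` as one or two isoforms, each a contiguous
#' substring of the truth sequence (uniform anchor, retained fraction drawn
#' from `truncation_frac_range`). A `chimera_rate` fraction of additional
#' transcripts are fusions of the 5' half of one truth locus with the 3' half
#' of another, with the junction recorded. Sequences are written as one FASTA
#' per k with Oases-style headers
#' `Locus_<i>_Transcript_<j>/<m>_Confidence_<c>_Length_<L>`.
#'
#' @param bundle a `truth_bundle` from [generate_truth_transcriptome()].
#' @param dir output directory for the per-k FASTA files.
#' @return the bundle with `assembly` (data.frame of every emitted transcript
#'   with provenance columns), `k_assembly_files` (named by k), `chimera_ids`
#'   and `truth_locus_of` (list: emitted id -> truth id(s)) populated.
#' @export
simulate_multik_assemblies <- function(bundle, dir = tempfile("kasm")) {
  stopifnot(inherits(bundle, "truth_bundle"))
  config <- bundle$config
  set.seed(stage_seed(config$seed, "assemblies"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- bundle$truth
  rows <- list()
  files <- character()

  for (k in config$kmer_list) {
    captured <- which(runif(nrow(truth)) < config$capture_prob_per_k)
    locus_counter <- 0L
    k_rows <- list()
    for (ti in captured) {
      locus_counter <- locus_counter + 1L
      L <- truth$length[ti]
      m <- 1L + rbinom(1L, 1L, 0.3)
      for (j in seq_len(m)) {
        frac <- runif(1, config$truncation_frac_range[1],
                      config$truncation_frac_range[2])
        keep <- max(min(L, 100L), round(frac * L))
        s <- if (L == keep) 1L else sample.int(L - keep + 1L, 1L)
        e <- s + keep - 1L
        conf <- max(0.001, round(runif(1), 3))
        k_rows[[length(k_rows) + 1L]] <- data.frame(
          kmer = k, locus_id = as.character(locus_counter),
          transcript_index = j, isoform_count = m, confidence = conf,
          sequence = substr(truth$sequence[ti], s, e),
          truth_locus = truth$id[ti], src_start = s, src_end = e,
          truth_locus2 = NA_character_, src_start2 = NA_integer_,
          src_end2 = NA_integer_, junction = NA_integer_,
          is_chimera = FALSE, stringsAsFactors = FALSE)
      }
    }
    n_chim <- if (length(captured)) rbinom(1L, length(captured),
                                           config$chimera_rate) else 0L
    for (ci in seq_len(n_chim)) {
      locus_counter <- locus_counter + 1L
      par <- sample.int(nrow(truth), 2L)
      LA <- truth$length[par[1]]; LB <- truth$length[par[2]]
      jA <- floor(LA / 2)                      # last base taken from parent A
      sB <- floor(LB / 2) + 1L
      seq <- paste0(substr(truth$sequence[par[1]], 1L, jA),
                    substr(truth$sequence[par[2]], sB, LB))
      conf <- max(0.001, round(runif(1), 3))
      k_rows[[length(k_rows) + 1L]] <- data.frame(
        kmer = k, locus_id = as.character(locus_counter),
        transcript_index = 1L, isoform_count = 1L, confidence = conf,
        sequence = seq,
        truth_locus = truth$id[par[1]], src_start = 1L, src_end = jA,
        truth_locus2 = truth$id[par[2]], src_start2 = sB, src_end2 = LB,
        junction = jA, is_chimera = TRUE, stringsAsFactors = FALSE)
    }
    if (length(k_rows)) {
      kdf <- do.call(rbind, k_rows)
      kdf$declared_length <- nchar(kdf$sequence)
      kdf$id <- sprintf("%d_Locus_%s_Transcript_%d", k, kdf$locus_id,
                        kdf$transcript_index)
      headers <- oases_header(as.integer(kdf$locus_id), kdf$transcript_index,
                              kdf$isoform_count, kdf$confidence,
                              kdf$declared_length)
      path <- file.path(dir, sprintf("assembly_k%d.fasta", k))
      write_fasta(setNames(kdf$sequence, headers), path)
      files[[as.character(k)]] <- path
      rows[[length(rows) + 1L]] <- kdf
    } else {
      path <- file.path(dir, sprintf("assembly_k%d.fasta", k))
      writeLines(character(), path)
      files[[as.character(k)]] <- path
    }
  }
  assembly <- do.call(rbind, rows)
  rownames(assembly) <- NULL
  bundle$assembly <- assembly
  bundle$k_assembly_files <- files
  bundle$chimera_ids <- assembly$id[assembly$is_chimera]
  tl <- lapply(seq_len(nrow(assembly)), function(i) {
    v <- assembly$truth_locus[i]
    if (!is.na(assembly$truth_locus2[i])) v <- c(v, assembly$truth_locus2[i])
    v
  })
  bundle$truth_locus_of <- setNames(tl, assembly$id)
  bundle
}

phred_to_char <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

#' Simulate expression-weighted paired-end reads
#'
#' Fragments are drawn from truth transcripts with probability proportional to
#' `expression_weight * length`; the two reads of a pair come from the
#' fragment ends, the second reverse-complemented. Per-base Phred scores
#' follow the configured per-cycle profile and substitution errors are
#' injected with probability `10^(-Q/10)`. Chimeric transcripts exist only in
#' the pseudo-assemblies, never in the truth set, so no simulated read spans a
#' planted junction — mapping reads back therefore produces the internal
#' coverage trough the chimera filter detects.
#'
#' @param bundle a `truth_bundle`.
#' @param dir output directory for FASTQ files.
#' @return the bundle with `fastq` (paths `mate1`, `mate2`, `singletons`) and
#'   `read_origins` (data.frame of fragment coordinates per pair) populated.
#' @export
simulate_reads <- function(bundle, dir = tempfile("reads")) {
  stopifnot(inherits(bundle, "truth_bundle"))
  config <- bundle$config
  set.seed(stage_seed(config$seed, "reads"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(mate1 = file.path(dir, "reads_1.fastq"),
                mate2 = file.path(dir, "reads_2.fastq"),
                singletons = file.path(dir, "reads_singletons.fastq"))
  n <- config$n_read_pairs
  rl <- config$read_length
  qp <- config$quality_profile
  if (n == 0L) {
    for (p in paths) writeLines(character(), p)
    bundle$fastq <- paths
    bundle$read_origins <- data.frame(read_id = character(),
                                      locus = character(), start = integer(),
                                      end = integer(), stringsAsFactors = FALSE)
    return(bundle)
  }
  truth <- bundle$truth
  p_tx <- truth$expression_weight * truth$length
  pick <- sample.int(nrow(truth), n, replace = TRUE, prob = p_tx)
  L <- truth$length[pick]
  ins <- pmin(pmax(round(rnorm(n, config$insert_mean, config$insert_sd)), rl), L)
  start <- floor(runif(n) * (L - ins + 1)) + 1L
  end <- start + ins - 1L

  cycle_mean <- qp$q_start + qp$q_slope * (seq_len(rl) - 1L)
  sim_mate <- function(raw_seq) {
    nb <- n * rl
    qmean <- matrix(rep(cycle_mean, times = n), nrow = rl)
    degraded <- which(runif(n) < qp$p_degraded)
    for (j in degraded) {
      onset <- sample.int(rl, 1L)
      qmean[onset:rl, j] <- qp$q_degraded
    }
    q <- round(as.vector(qmean) + rnorm(nb, 0, qp$q_sd))
    q <- pmin(pmax(q, 2L), 40L)
    bases <- strsplit(paste(raw_seq, collapse = ""), "")[[1]]
    err <- runif(nb) < 10^(-q / 10)
    if (any(err)) {
      sub <- vapply(bases[err],
                    function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
      bases[err] <- sub
    }
    isn <- runif(nb) < qp$n_rate
    bases[isn] <- "N"; q[isn] <- 2L
    qm <- matrix(q, nrow = rl)
    bm <- matrix(bases, nrow = rl)
    list(seq = apply(bm, 2, paste, collapse = ""),
         qual = apply(qm, 2, function(v) rawToChar(as.raw(v + 33L))))
  }
  raw1 <- substr(truth$sequence[pick], start, start + rl - 1L)
  raw2 <- revcomp(substr(truth$sequence[pick], end - rl + 1L, end))
  m1 <- sim_mate(raw1)
  m2 <- sim_mate(raw2)
  ids <- sprintf("read%07d", seq_len(n))
  write_fastq_chr <- function(id, seq, qual, path) {
    out <- character(4L * length(id))
    out[seq(1, length(out), 4)] <- paste0("@", id)
    out[seq(2, length(out), 4)] <- seq
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- qual
    writeLines(out, path)
  }
  write_fastq_chr(paste0(ids, "/1"), m1$seq, m1$qual, paths$mate1)
  write_fastq_chr(paste0(ids, "/2"), m2$seq, m2$qual, paths$mate2)
  writeLines(character(), paths$singletons)
  bundle$fastq <- paths
  bundle$read_origins <- data.frame(
    read_id = ids, locus = truth$id[pick], start = start, end = end,
    stringsAsFactors = FALSE)
  bundle
}

#' Place simulated reads on a transcript set and write a SAM file
#'
#' Truth-guided placement: each read mate is assigned to one transcript whose
#' recorded source interval on the read's truth locus fully contains the mate
#' (drawn uniformly at random when several transcripts qualify, as an
#' end-to-end short-read mapper does with multi-mapping reads), with position
#' translated into transcript coordinates and a fully-matching CIGAR. Reads
#' overlapping a chimeric junction on the truth side map to neither half and
#' are dropped, which is exactly the physical signal (no junction-spanning
#' pairs) the coverage filter looks for. No alignment algorithm is involved;
#' this stands in for an external short-read mapper when exercising the
#' coverage stage on synthetic data.
#'
#' @param bundle a `truth_bundle` with reads and assemblies simulated.
#' @param transcript_ids ids (rows of `bundle$assembly`) to use as mapping
#'   references, e.g. the ids surviving the merge stage.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
simulate_alignments <- function(bundle, transcript_ids, path) {
  stopifnot(inherits(bundle, "truth_bundle"), !is.null(bundle$read_origins))
  asm <- bundle$assembly[match(transcript_ids, bundle$assembly$id), ,
                         drop = FALSE]
  if (anyNA(asm$id)) stop("unknown transcript ids in 'transcript_ids'")
  rl <- bundle$config$read_length
  ro <- bundle$read_origins
  ## mate intervals on the truth locus
  mates <- rbind(
    data.frame(qname = paste0(ro$read_id, "/1"), locus = ro$locus,
               s = ro$start, e = ro$start + rl - 1L, rev = FALSE,
               stringsAsFactors = FALSE),
    data.frame(qname = paste0(ro$read_id, "/2"), locus = ro$locus,
               s = ro$end - rl + 1L, e = ro$end, rev = TRUE,
               stringsAsFactors = FALSE))
  set.seed(stage_seed(bundle$config$seed, "alignments"))
  segments <- list()
  for (i in seq_len(nrow(asm))) {
    segments[[length(segments) + 1L]] <- data.frame(
      tid = asm$id[i], locus = asm$truth_locus[i], src_s = asm$src_start[i],
      src_e = asm$src_end[i], off = 0L, stringsAsFactors = FALSE)
    if (!is.na(asm$truth_locus2[i]))
      segments[[length(segments) + 1L]] <- data.frame(
        tid = asm$id[i], locus = asm$truth_locus2[i],
        src_s = asm$src_start2[i], src_e = asm$src_end2[i],
        off = asm$junction[i],     # part B starts right after the junction
        stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, segments)
  ## every (mate, segment) containment candidate, then one draw per mate
  cand <- list()
  for (i in seq_len(nrow(segments))) {
    hit <- which(mates$locus == segments$locus[i] &
                 mates$s >= segments$src_s[i] & mates$e <= segments$src_e[i])
    if (!length(hit)) next
    cand[[length(cand) + 1L]] <- data.frame(
      mate = hit, seg = i, stringsAsFactors = FALSE)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", asm$id, nchar(asm$sequence)))
  body <- character()
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    cand <- cand[!duplicated(cand$mate), , drop = FALSE]
    pos <- mates$s[cand$mate] - segments$src_s[cand$seg] + 1L +
      segments$off[cand$seg]
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                    mates$qname[cand$mate],
                    ifelse(mates$rev[cand$mate], 16L, 0L),
                    segments$tid[cand$seg], pos, rl)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a machine-readable truth manifest
#'
#' Tab-separated rows describing every planted feature: one row per truth
#' locus, microsatellite, chimera, rRNA tag and emitted k-assembly transcript.
#'
#' @param bundle a `truth_bundle`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(bundle, path) {
  rows <- data.frame(type = "truth", id = bundle$truth$id,
                     detail = sprintf("length=%d;weight=%.6g",
                                      bundle$truth$length,
                                      bundle$truth$expression_weight),
                     stringsAsFactors = FALSE)
  if (nrow(bundle$msat_loci))
    rows <- rbind(rows, data.frame(
      type = "msat", id = bundle$msat_loci$transcript_id,
      detail = sprintf("motif=%s;start=%d;end=%d;units=%d",
                       bundle$msat_loci$motif, bundle$msat_loci$start,
                       bundle$msat_loci$end, bundle$msat_loci$unit_count),
      stringsAsFactors = FALSE))
  if (length(bundle$rrna_ids))
    rows <- rbind(rows, data.frame(type = "rrna", id = bundle$rrna_ids,
                                   detail = "", stringsAsFactors = FALSE))
  if (!is.null(bundle$assembly)) {
    a <- bundle$assembly
    rows <- rbind(rows, data.frame(
      type = ifelse(a$is_chimera, "chimera", "copy"), id = a$id,
      detail = ifelse(a$is_chimera,
                      sprintf("parents=%s+%s;junction0=%d", a$truth_locus,
                              a$truth_locus2, a$junction - 1L),
                      sprintf("truth=%s;src=%d-%d", a$truth_locus,
                              a$src_start, a$src_end)),
      stringsAsFactors = FALSE))
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
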