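## Independent brute-force oracles used to cross-check the package's own
## implementations. These deliberately use different algorithms from the
## production code paths.

## N50 by direct definition: largest observed length L such that sequences of
## length >= L hold at least half the total bases
oracle_n50 <- function(lengths) {
  total <- sum(as.numeric(lengths))
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand)
    if (sum(as.numeric(lengths[lengths >= L])) >= total / 2) return(L)
  stop("unreachable")
}

## semi-global alignment score by affine-gap DP (Gotoh), pattern (shorter)
## global, subject local; match +1, mismatch -1, gap of length L costs 1 + L
oracle_semiglobal_score <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  p <- strsplit(a, "")[[1]]; s <- strsplit(b, "")[[1]]
  n <- length(p); m <- length(s)
  NEG <- -1e9
  gap <- function(L) 1 + L
  M <- matrix(NEG, n + 1, m + 1)   # p[i] aligned to s[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in subject (p[i] unmatched)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in pattern (s[j] unmatched)
  M[1, ] <- 0                      # free subject prefix
  for (i in seq_len(n)) X[i + 1, 1] <- -gap(i)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (p[i] == s[j]) 1 else -1
      M[i + 1, j + 1] <- sc + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap(1), X[i, j + 1] - 1)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap(1), Y[i + 1, j] - 1)
    }
  }
  max(M[n + 1, ], X[n + 1, ], Y[n + 1, ])   # free subject suffix
}

## brute-force perfect-microsatellite scan: test every motif length and start
## position, extend maximally, keep primitive motifs meeting the threshold
oracle_scan_msat <- function(seq, min_units = c(`2` = 10L, `3` = 7L, `4` = 5L)) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  hits <- list()
  for (k in as.integer(names(min_units))) {
    need <- min_units[[as.character(k)]]
    pos <- 1L
    while (pos + k * need - 1L <= n) {
      units <- 1L
      while (pos + (units + 1L) * k - 1L <= n &&
             all(x[pos:(pos + k - 1L)] ==
                 x[(pos + units * k):(pos + (units + 1L) * k - 1L)]))
        units <- units + 1L
      motif <- paste(x[pos:(pos + k - 1L)], collapse = "")
      left_ext <- pos > k &&
        all(x[(pos - k):(pos - 1L)] == x[pos:(pos + k - 1L)])
      ## partial left extension shifts the maximal region start
      partial_left <- pos > 1L && x[pos - 1L] == x[pos - 1L + k]
      if (units >= need && !grepl("N", motif, fixed = TRUE) &&
          oracle_primitive(motif) && !left_ext && !partial_left) {
        hits[[length(hits) + 1L]] <- data.frame(
          motif = canonical_motif(motif), start = pos,
          end = pos + units * k - 1L, unit_count = units,
          stringsAsFactors = FALSE)
      }
      pos <- if (units >= need) pos + units * k else pos + 1L
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), unit_count = integer(),
                      stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_primitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d) next
    if (motif == strrep(substr(motif, 1, d), k / d)) return(FALSE)
  }
  TRUE
}

## greedy clustering oracle: plain loops, all-pairs identity, no prefilter
oracle_greedy_clusters <- function(seqs, threshold = 0.95) {
  ord <- order(-nchar(seqs), seq_along(seqs))
  reps <- integer()
  assign <- integer(length(seqs))
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      if (pairwise_identity(seqs[i], seqs[r]) >= threshold) {
        assign[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- i
    }
  }
  assign   # index of cluster representative for each input sequence
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

## substitute exactly k positions (spaced >= 3 apart) with a different base
mutate_subs <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  pos <- sort(sample(seq(1, length(x), by = 3), k))
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}

make_read_set <- function(seqs, quals, ids = sprintf("r%03d", seq_along(seqs))) {
  multika:::read_set(ids, seqs, quals)
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_loci = 25L, length_range = c(150L, 1200L),
                   n_read_pairs = 4000L, capture_prob_per_k = 0.8,
                   chimera_rate = 0.05, seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, args))
}
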