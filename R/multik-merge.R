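## Additive multiple-k merging: parse Oases-style headers, pick one
## representative transcript per locus, then collapse redundancy across all
## k-assemblies by greedy incremental clustering at 95% identity, keeping the
## longest transcript of each cluster.

#' Parse an Oases-style FASTA header
#'
#' Headers follow the dialect
#' `Locus_<i>_Transcript_<j>/<m>_Confidence_<c>_Length_<L>`.
#'
#' @param header header string (without `>`).
#' @return list with `locus_id`, `transcript_index`, `isoform_count`,
#'   `confidence` and `declared_length`.
#' @export
parse_oases_header <- function(header) {
  pat <- "^Locus_([0-9]+)_Transcript_([0-9]+)/([0-9]+)_Confidence_([0-9.]+)_Length_([0-9]+)$"
  m <- regmatches(header, regexec(pat, header))[[1]]
  if (length(m) != 6L)
    stop(sprintf("malformed Oases header: '%s'", header), call. = FALSE)
  idx <- as.integer(m[3]); cnt <- as.integer(m[4])
  if (idx > cnt)
    stop(sprintf("malformed Oases header (transcript index %d > isoform count %d): '%s'",
                 idx, cnt, header), call. = FALSE)
  list(locus_id = m[2], transcript_index = idx, isoform_count = cnt,
       confidence = as.numeric(m[5]), declared_length = as.integer(m[6]))
}

#' Load one k-assembly FASTA into a transcript table
#'
#' Every header is parsed with [parse_oases_header()], the declared length is
#' checked against the sequence, and transcripts shorter than `min_len`
#' (default 100 bp) are discarded at load.
#'
#' @param path FASTA path.
#' @param kmer the k value this assembly was built with.
#' @param min_len minimum transcript length kept.
#' @return data.frame with columns `id` (`<k>_Locus_<i>_Transcript_<j>`),
#'   `kmer`, `locus_id`, `transcript_index`, `isoform_count`, `confidence`,
#'   `declared_length`, `sequence`.
#' @export
read_kmer_assembly <- function(path, kmer, min_len = 100L) {
  seqs <- read_fasta(path)
  if (!length(seqs))
    return(data.frame(id = character(), kmer = integer(),
                      locus_id = character(), transcript_index = integer(),
                      isoform_count = integer(), confidence = numeric(),
                      declared_length = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  meta <- lapply(names(seqs), parse_oases_header)
  df <- data.frame(
    kmer = as.integer(kmer),
    locus_id = vapply(meta, `[[`, character(1), "locus_id"),
    transcript_index = vapply(meta, `[[`, integer(1), "transcript_index"),
    isoform_count = vapply(meta, `[[`, integer(1), "isoform_count"),
    confidence = vapply(meta, `[[`, numeric(1), "confidence"),
    declared_length = vapply(meta, `[[`, integer(1), "declared_length"),
    sequence = unname(seqs),
    stringsAsFactors = FALSE)
  bad <- which(df$declared_length != nchar(df$sequence))
  if (length(bad))
    stop(sprintf("header/sequence length mismatch for '%s' (declared %d, actual %d)",
                 names(seqs)[bad[1]], df$declared_length[bad[1]],
                 nchar(df$sequence[bad[1]])))
  df$id <- sprintf("%d_Locus_%s_Transcript_%d", df$kmer, df$locus_id,
                   df$transcript_index)
  df <- df[nchar(df$sequence) >= min_len, , drop = FALSE]
  rownames(df) <- NULL
  df[, c("id", "kmer", "locus_id", "transcript_index", "isoform_count",
         "confidence", "declared_length", "sequence")]
}

#' Select one representative transcript per locus
#'
#' Within each locus of one k-assembly the representative is chosen by
#' maximum sequence length, ties broken by maximum confidence, remaining ties
#' by lowest transcript index.
#'
#' @param assembly data.frame as returned by [read_kmer_assembly()].
#' @return data.frame with one row per (kmer, locus).
#' @export
select_representatives <- function(assembly) {
  if (!nrow(assembly)) return(assembly)
  key <- paste(assembly$kmer, assembly$locus_id, sep = "\r")
  ord <- order(key, -nchar(assembly$sequence), -assembly$confidence,
               assembly$transcript_index)
  sorted <- assembly[ord, , drop = FALSE]
  keep <- sorted[!duplicated(key[ord]), , drop = FALSE]
  keep <- keep[order(match(keep$id, assembly$id)), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Pairwise nucleotide identity under the clustering convention
#'
#' Identity is the number of identical aligned bases divided by the length of
#' the *shorter* sequence, from a semi-global alignment (the shorter sequence
#' aligned end-to-end against a local region of the longer; match +1,
#' mismatch -1, gap open -2, gap extend -1 per additional base). Under this
#' denominator an exact substring scores identity 1 against its parent, which
#' is what lets a high-k fragment collapse into its full-length low-k copy.
#'
#' @param a,b non-empty nucleotide sequences.
#' @return identity in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("pairwise_identity: empty sequence")
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (a == b) return(1)
  pa <- pairwiseAlignment(
    a, b, type = "global-local",
    substitutionMatrix = nucleotideSubstitutionMatrix(match = 1, mismatch = -1),
    gapOpening = 1, gapExtension = 1)
  nmatch(pa) / nchar(a)
}

## all overlapping k-mers of a sequence (character k-mers, unique)
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Merge representative transcripts across k-assemblies by greedy clustering
#'
#' Implements the additive multiple-k merge: transcripts from all k values are
#' pooled, sorted by length descending (ties by input order), and clustered
#' greedily — each transcript joins the first existing cluster whose
#' representative it matches at `identity_threshold` or better under
#' [pairwise_identity()], otherwise it founds a new cluster. The cluster
#' representative is the longest member by construction and forms the merged,
#' non-redundant output set.
#'
#' A shared-word prefilter (`word_size`, default 11) skips alignment for pairs
#' that share no exact word; at a 95% identity threshold and a 100 bp minimum
#' length every qualifying pair is guaranteed a clean run longer than the
#' word, so the prefilter cannot change the result.
#'
#' @param representatives data.frame of transcripts (columns `id`, `kmer`,
#'   `sequence`; typically one representative per locus per k).
#' @param identity_threshold clustering identity cut-off in (0, 1].
#' @param word_size prefilter word length; set to `NA` to disable.
#' @return a `merged_set`: list with `transcripts` (data.frame of cluster
#'   representatives, input-pool order of founding), `clusters` (data.frame:
#'   `cluster`, `representative_id`, `member_id`, `identity`) and `provenance`
#'   (data.frame: `id`, `kmer`, `original_id`).
#' @export
cluster_and_merge <- function(representatives, identity_threshold = 0.95,
                              word_size = 11L) {
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]", call. = FALSE)
  df <- representatives
  if (!nrow(df))
    stop("cluster_and_merge: no input transcripts", call. = FALSE)
  ord <- order(-nchar(df$sequence), seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  rep_idx <- integer()          # row index (in df) of each cluster rep
  rep_words <- list()           # word set per cluster rep
  assign_cluster <- integer(n)
  identity_to_rep <- numeric(n)
  use_words <- !is.na(word_size)
  for (i in seq_len(n)) {
    s <- df$sequence[i]
    words <- if (use_words) seq_kmers(s, word_size) else NULL
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      if (use_words && !any(words %in% rep_words[[ci]])) next
      idt <- pairwise_identity(s, df$sequence[rep_idx[ci]])
      if (idt >= identity_threshold) {
        assign_cluster[i] <- ci
        identity_to_rep[i] <- idt
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      rep_words[[length(rep_idx)]] <- words
      assign_cluster[i] <- length(rep_idx)
      identity_to_rep[i] <- 1
    }
  }
  clusters <- data.frame(
    cluster = assign_cluster,
    representative_id = df$id[rep_idx][assign_cluster],
    member_id = df$id,
    identity = identity_to_rep,
    stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$cluster), , drop = FALSE]
  rownames(clusters) <- NULL
  out <- df[rep_idx, , drop = FALSE]
  rownames(out) <- NULL
  prov <- data.frame(id = out$id,
                     kmer = if ("kmer" %in% names(out)) out$kmer else NA_integer_,
                     original_id = out$id, stringsAsFactors = FALSE)
  structure(list(transcripts = out, clusters = clusters, provenance = prov),
            class = "merged_set")
}

#' @export
print.merged_set <- function(x, ...) {
  cat(sprintf("merged_set: %d transcripts in %d clusters (from %d inputs)\n",
              nrow(x$transcripts), max(x$clusters$cluster),
              nrow(x$clusters)))
  invisible(x)
}

#' Write a merged set: FASTA plus a cluster table
#'
#' @param merged a `merged_set` from [cluster_and_merge()].
#' @param fasta_path,table_path output paths (either may be `NULL` to skip).
#' @return invisible list of the paths written.
#' @export
write_merged_set <- function(merged, fasta_path = NULL, table_path = NULL) {
  if (!is.null(fasta_path))
    write_fasta(setNames(merged$transcripts$sequence, merged$transcripts$id),
                fasta_path)
  if (!is.null(table_path))
    write.table(merged$clusters, table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(fasta = fasta_path, table = table_path))
}
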