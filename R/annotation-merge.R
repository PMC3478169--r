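## Annotation merging: 12-column BLAST tabular parsing, top-hit selection,
## the annotated-set e-value rule across multiple reference databases,
## unique-subject counting with a transcriptome-coverage estimate, and an ORF
## based completeness classification.

BLAST_COLS <- c("query_id", "subject_id", "pct_identity", "align_len",
                "mismatches", "gap_opens", "q_start", "q_end", "s_start",
                "s_end", "evalue", "bitscore")

#' Parse a 12-column BLAST tabular file
#'
#' @param path path to a `-outfmt 6` style file.
#' @param source_db label for the reference set the search ran against (e.g.
#'   `"NR"`, `"UniGene-chicken"`).
#' @return data.frame with the standard 12 columns plus `source_db`; e-values
#'   in scientific notation are parsed as numerics.
#' @export
parse_blast_tabular <- function(path, source_db) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- setNames(
    data.frame(character(), character(), numeric(), integer(), integer(),
               integer(), integer(), integer(), integer(), integer(),
               numeric(), numeric(), stringsAsFactors = FALSE), BLAST_COLS)
  empty$source_db <- character()
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop(sprintf("BLAST tabular parse error at line %d of '%s': %d columns (expected 12)",
                 bad[1], path, lengths(fields)[bad[1]]), call. = FALSE)
  m <- do.call(rbind, fields)
  df <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), align_len = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (anyNA(df$evalue) || any(df$evalue < 0))
    stop(sprintf("invalid e-value in '%s'", path), call. = FALSE)
  df$source_db <- source_db
  df
}

#' Best hit per query
#'
#' Minimum e-value; ties broken by maximum bitscore, remaining ties by file
#' order.
#'
#' @param hits data.frame of BLAST hits (one source).
#' @return data.frame with one row per `query_id`, in first-appearance order.
#' @export
top_hit_per_query <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query_id, hits$evalue, -hits$bitscore,
               seq_len(nrow(hits)))
  sorted <- hits[ord, , drop = FALSE]
  best <- sorted[!duplicated(sorted$query_id), , drop = FALSE]
  best <- best[order(match(best$query_id, hits$query_id)), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Build the annotated transcript set across reference databases
#'
#' A transcript is annotated if it has at least one hit at or below
#' `evalue_max` in at least one source (the usual BLAST cut-off convention;
#' set `strict = TRUE` for strictly-below semantics).
#'
#' @param hits data.frame of hits from all sources (with `source_db`), e.g.
#'   several [parse_blast_tabular()] results row-bound.
#' @param transcript_ids optional full id universe so unannotated transcripts
#'   appear with `annotated = FALSE`.
#' @param evalue_max significance threshold.
#' @param strict if `TRUE`, require `evalue < evalue_max` instead of `<=`.
#' @return list with `records` (data.frame: `transcript_id`, `annotated`,
#'   `sources_matched` semicolon-joined, one top-hit column pair
#'   `<source>_subject` / `<source>_evalue` per source), `per_source` counts
#'   and `n_annotated` (the union count).
#' @export
build_annotated_set <- function(hits, transcript_ids = NULL,
                                evalue_max = 1e-5, strict = FALSE) {
  sig <- if (strict) hits$evalue < evalue_max else hits$evalue <= evalue_max
  hits <- hits[sig, , drop = FALSE]
  sources <- unique(hits$source_db)
  ids <- transcript_ids %||% unique(hits$query_id)
  records <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  matched <- matrix(FALSE, nrow = length(ids), ncol = length(sources),
                    dimnames = list(NULL, sources))
  for (src in sources) {
    top <- top_hit_per_query(hits[hits$source_db == src, , drop = FALSE])
    m <- match(ids, top$query_id)
    records[[paste0(src, "_subject")]] <- top$subject_id[m]
    records[[paste0(src, "_evalue")]] <- top$evalue[m]
    matched[, src] <- !is.na(m)
  }
  records$annotated <- rowSums(matched) > 0
  records$sources_matched <- apply(matched, 1, function(r)
    paste(sources[r], collapse = ";"))
  list(records = records,
       per_source = colSums(matched),
       n_annotated = sum(records$annotated))
}

#' Count distinct subject genes among top hits
#'
#' @param hits data.frame of BLAST hits.
#' @param source_db restrict to this source label (optional when `hits` holds
#'   a single source).
#' @return number of distinct `subject_id`s among per-query top hits.
#' @export
count_unique_subjects <- function(hits, source_db = NULL) {
  if (!is.null(source_db))
    hits <- hits[hits$source_db == source_db, , drop = FALSE]
  if (!nrow(hits)) return(0L)
  length(unique(top_hit_per_query(hits)$subject_id))
}

#' Transcriptome coverage estimate
#'
#' The fraction of a reference gene set matched by distinct subjects, as a
#' percentage: `unique_subjects / db_size * 100`.
#'
#' @param unique_subjects distinct reference genes hit.
#' @param db_size size of the reference gene set.
#' @return percentage.
#' @export
coverage_estimate <- function(unique_subjects, db_size) {
  stopifnot(db_size > 0)
  100 * unique_subjects / db_size
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## ORFs of one frame of a forward-oriented sequence: codon segments between
## stops; candidate = first ATG (if any) to segment end, stop codon included
frame_orfs <- function(seq, offset) {
  n <- nchar(seq)
  n_codon <- (n - offset) %/% 3L
  if (n_codon < 1L) return(NULL)
  starts <- offset + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  is_stop <- codons %in% STOP_CODONS
  seg_id <- cumsum(c(TRUE, is_stop[-n_codon]))   # stop codon ends its segment
  out <- list()
  for (s in split(seq_len(n_codon), seg_id)) {
    stop_here <- is_stop[s[length(s)]]
    atg <- s[codons[s] == "ATG"]
    ## the coding candidate needs codons before any terminal stop
    first <- if (length(atg)) atg[1] else s[1]
    if (stop_here && first == s[length(s)]) next   # lone stop codon
    out[[length(out) + 1L]] <- list(
      start = starts[first], end = starts[s[length(s)]] + 2L,
      has_start = length(atg) > 0L, has_stop = stop_here)
  }
  out
}

#' Classify ORF completeness of a transcript
#'
#' Locates the longest open reading frame over all six frames. The call is
#' `full_length` when the ORF has both a start and a stop codon and, if a
#' protein hit is supplied, the hit covers at least 90% of the subject;
#' `putative_full_length` when the ORF is complete but subject coverage is in
#' \[50%, 90%); otherwise `partial`.
#'
#' @param sequence transcript sequence (A/C/G/T/N).
#' @param top_hit optional list/row with `s_start`, `s_end` and
#'   `subject_length` describing the best protein hit.
#' @param full_cov,putative_cov subject-coverage thresholds for the two
#'   complete classes.
#' @return an `orf_call`: list with `frame` (-3..-1, +1..+3), `orf_start`,
#'   `orf_end` (1-based transcript coordinates, start < end), `has_start_codon`,
#'   `has_stop_codon`, `class`.
#' @export
classify_orf_completeness <- function(sequence, top_hit = NULL,
                                      full_cov = 0.9, putative_cov = 0.5) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  if (nchar(sequence) < 3L) stop("sequence shorter than one codon")
  n <- nchar(sequence)
  rc <- revcomp(sequence)
  best <- NULL
  ## longest wins; on length ties a complete ORF (start + stop) beats an open
  ## one, then earlier frames (forward before reverse) stand
  better <- function(o, best) {
    if (is.null(best)) return(TRUE)
    lo <- o$end - o$start; lb <- best$end - best$start
    if (lo != lb) return(lo > lb)
    (o$has_start + o$has_stop) > (best$has_start + best$has_stop)
  }
  for (fr in 1:3) {
    for (o in frame_orfs(sequence, fr - 1L)) {
      o$frame <- fr
      if (better(o, best)) best <- o
    }
    for (o in frame_orfs(rc, fr - 1L)) {
      ## map back: position p on the reverse complement is n - p + 1 forward
      mapped <- list(start = n - o$end + 1L, end = n - o$start + 1L,
                     has_start = o$has_start, has_stop = o$has_stop,
                     frame = -fr)
      if (better(mapped, best)) best <- mapped
    }
  }
  if (is.null(best))
    return(structure(list(frame = NA_integer_, orf_start = NA_integer_,
                          orf_end = NA_integer_, has_start_codon = FALSE,
                          has_stop_codon = FALSE, class = "partial"),
                     class = "orf_call"))
  complete <- best$has_start && best$has_stop
  cls <- "partial"
  if (complete) {
    if (is.null(top_hit)) {
      cls <- "full_length"
    } else {
      cov <- (abs(top_hit$s_end - top_hit$s_start) + 1) / top_hit$subject_length
      cls <- if (cov >= full_cov) "full_length"
             else if (cov >= putative_cov) "putative_full_length"
             else "partial"
    }
  }
  structure(list(frame = best$frame, orf_start = best$start,
                 orf_end = best$end, has_start_codon = best$has_start,
                 has_stop_codon = best$has_stop, class = cls),
            class = "orf_call")
}
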