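## Feature scanning: perfect microsatellite (SSR) detection at the study's
## unit-count thresholds (10 di-, 7 tri-, 5 tetranucleotide units),
## RepeatMasker .out parsing, a repeat-landscape summary, and rRNA flagging.

## minimal period of a motif: smallest d dividing k with motif == unit^*
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d != 0L) next
    if (motif == strrep(substr(motif, 1L, d), k / d)) return(FALSE)
  }
  TRUE
}

rotations <- function(motif) {
  k <- nchar(motif)
  vapply(seq_len(k), function(i)
    paste0(substr(motif, i, k), substr(motif, 1L, i - 1L)), character(1))
}

#' Canonical form of a microsatellite motif
#'
#' The lexicographically smallest string among all rotations of the motif and
#' all rotations of its reverse complement, so one repeat run yields one
#' canonical hit regardless of reading phase or strand.
#'
#' @param motif motif string over ACGT.
#' @return canonical motif string.
#' @export
canonical_motif <- function(motif) {
  min(c(rotations(motif), rotations(revcomp(motif))))
}

scan_one_sequence <- function(seq, id, min_units) {
  n <- nchar(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hits <- list()
  for (k in as.integer(names(min_units))) {
    need <- min_units[[as.character(k)]]
    if (n < k * need) next
    eq <- x[seq_len(n - k)] == x[(k + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      region_len <- r$lengths[j] + k          # bases in the periodic region
      units <- region_len %/% k
      if (units < need) next
      s0 <- starts[j]
      motif <- substr(seq, s0, s0 + k - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      if (!is_primitive_motif(motif)) next    # reported at its true period
      hits[[length(hits) + 1L]] <- data.frame(
        transcript_id = id, motif = canonical_motif(motif), start = s0,
        end = s0 + units * k - 1L, unit_count = units, length = units * k,
        stringsAsFactors = FALSE)
    }
  }
  hits
}

#' Scan transcripts for perfect microsatellites
#'
#' Reports every maximal perfect tandem repeat of a primitive 2-4 bp motif
#' meeting its unit-count threshold (defaults 10, 7 and 5 units for di-, tri-
#' and tetranucleotides, i.e. a minimum span of 20 bp). A run is reported
#' once, under the canonical motif (smallest rotation over both strands), with
#' 1-based inclusive coordinates anchored at the leftmost full unit;
#' non-primitive motifs (e.g. a poly-A run read as "AA") are suppressed
#' because the same run is reported at its true period. Hits are sorted by
#' transcript and start.
#'
#' @param transcripts named character vector of sequences, or a FASTA path.
#' @param min_units named list/vector of unit thresholds by motif length.
#' @return data.frame with `transcript_id`, `motif`, `start`, `end`,
#'   `unit_count`, `length`.
#' @export
scan_microsatellites <- function(transcripts,
                                 min_units = c(`2` = 10L, `3` = 7L, `4` = 5L)) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      is.null(names(transcripts)) && file.exists(transcripts))
    transcripts <- read_fasta(transcripts)
  if (any(unlist(min_units) < 1)) stop("min_units must be positive")
  names(transcripts) <- sub("\\s.*$", "", names(transcripts))
  hits <- list()
  for (i in seq_along(transcripts))
    hits <- c(hits, scan_one_sequence(toupper(transcripts[[i]]),
                                      names(transcripts)[i], min_units))
  if (!length(hits))
    return(data.frame(transcript_id = character(), motif = character(),
                      start = integer(), end = integer(),
                      unit_count = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse a RepeatMasker .out annotation file
#'
#' Expects the standard layout: two header lines and a blank line, then one
#' whitespace-delimited annotation row per repeat. Query coordinates are kept
#' as-is (1-based inclusive).
#'
#' @param path path to the `.out` file.
#' @return data.frame with `transcript_id`, `repeat_name`,
#'   `repeat_class_family`, `start`, `end`, `divergence_pct`.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  body_idx <- which(seq_along(lines) > 3L & nzchar(trimws(lines)))
  empty <- data.frame(transcript_id = character(), repeat_name = character(),
                      repeat_class_family = character(), start = integer(),
                      end = integer(), divergence_pct = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(body_idx)) return(empty)
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 14L)
      stop(sprintf("malformed RepeatMasker line %d in '%s': %d columns",
                   i, path, length(f)), call. = FALSE)
    data.frame(transcript_id = f[5], repeat_name = f[10],
               repeat_class_family = f[11], start = as.integer(f[6]),
               end = as.integer(f[7]), divergence_pct = as.numeric(f[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## class/family string -> (parent category, leaf category) of the summary tree
repeat_category <- function(class_family) {
  cf <- class_family
  leaf <- character(length(cf))
  parent <- character(length(cf))
  pick <- function(pat) grepl(pat, cf, ignore.case = TRUE)
  parent[] <- "Unclassified interspersed repeat"
  leaf[] <- "Unclassified interspersed repeat"
  sine <- pick("^SINE")
  parent[sine] <- "Retroelements"; leaf[sine] <- "SINEs"
  line <- pick("^LINE")
  parent[line] <- "Retroelements"; leaf[line] <- "LINEs"
  leaf[line & pick("L2|CR1|Rex")] <- "L2/CR1/Rex"
  leaf[line & pick("RTE|Bov-B")] <- "RTE/Bov-B"
  leaf[line & pick("L1|CIN4")] <- "L1/CIN4"
  ltr <- pick("^LTR")
  parent[ltr] <- "Retroelements"; leaf[ltr] <- "LTR elements"
  leaf[ltr & pick("Bel|Pao")] <- "Bel/Pao"
  leaf[ltr & pick("Copia")] <- "Ty1/Copia"
  leaf[ltr & pick("Gypsy|DIRS")] <- "Gypsy/DIRS1"
  leaf[ltr & pick("ERV|Retrovir")] <- "Retroviral"
  dna <- pick("^DNA")
  parent[dna] <- "DNA transposons"; leaf[dna] <- "DNA transposons"
  leaf[dna & pick("hAT|Hobo|Activator")] <- "Hobo-Activator"
  leaf[dna & pick("TcMar|Tc1|IS630|Pogo")] <- "Tc1-IS630-Pogo"
  leaf[dna & pick("PiggyBac")] <- "PiggyBac"
  leaf[dna & pick("Harbinger|Tourist|PIF")] <- "Tourist/Harbinger"
  srna <- pick("RNA$|^snRNA|^tRNA|^scRNA|^srpRNA|^rRNA")
  parent[srna] <- "Small RNA"; leaf[srna] <- "Small RNA"
  sat <- pick("^Satellite")
  parent[sat] <- "Satellites"; leaf[sat] <- "Satellites"
  simp <- pick("^Simple_repeat")
  parent[simp] <- "Simple repeats"; leaf[simp] <- "Simple repeats"
  lowc <- pick("^Low_complexity")
  parent[lowc] <- "Low complexity"; leaf[lowc] <- "Low complexity"
  data.frame(parent = parent, leaf = leaf, stringsAsFactors = FALSE)
}

## bases occupied by a feature set, overlaps merged per transcript
occupied_bases <- function(features) {
  if (!nrow(features)) return(0L)
  by_tx <- split(features, features$transcript_id)
  sum(vapply(by_tx, function(f)
    sum(width(reduce(IRanges(f$start, f$end)))), numeric(1)))
}

#' Repeat-landscape summary table
#'
#' Per category of the standard repeat tree (retroelements with SINE/LINE/LTR
#' subdivisions, DNA transposons and their families, small RNA, satellites,
#' simple repeats, low complexity): element count, bases occupied
#' (within-category overlaps merged per transcript), and percent of
#' `total_bases`. Parent rows aggregate their leaves; unknown class strings
#' fall under "Unclassified interspersed repeat".
#'
#' @param features data.frame from [parse_repeatmasker_out()].
#' @param total_bases total assembly size in bases.
#' @return data.frame with `category`, `n_elements`, `length_occupied`,
#'   `pct_of_sequence` (rounded to 2 decimals).
#' @export
summarise_repeats <- function(features, total_bases) {
  stopifnot(total_bases > 0)
  cat_order <- c("Retroelements", "SINEs", "LINEs", "L2/CR1/Rex", "RTE/Bov-B",
                 "L1/CIN4", "LTR elements", "Bel/Pao", "Ty1/Copia",
                 "Gypsy/DIRS1", "Retroviral", "DNA transposons",
                 "Hobo-Activator", "Tc1-IS630-Pogo", "PiggyBac",
                 "Tourist/Harbinger", "Unclassified interspersed repeat",
                 "Small RNA", "Satellites", "Simple repeats", "Low complexity")
  leaf_parent <- c("SINEs" = "Retroelements", "LINEs" = "Retroelements",
                   "L2/CR1/Rex" = "LINEs", "RTE/Bov-B" = "LINEs",
                   "L1/CIN4" = "LINEs", "LTR elements" = "Retroelements",
                   "Bel/Pao" = "LTR elements", "Ty1/Copia" = "LTR elements",
                   "Gypsy/DIRS1" = "LTR elements",
                   "Retroviral" = "LTR elements",
                   "Hobo-Activator" = "DNA transposons",
                   "Tc1-IS630-Pogo" = "DNA transposons",
                   "PiggyBac" = "DNA transposons",
                   "Tourist/Harbinger" = "DNA transposons")
  if (nrow(features)) {
    cats <- repeat_category(features$repeat_class_family)
  } else {
    cats <- data.frame(parent = character(), leaf = character())
  }
  stat_for <- function(name) {
    in_cat <- which(cats$leaf == name | cats$parent == name |
                    (cats$leaf %in% names(leaf_parent) &
                     leaf_parent[cats$leaf] == name))
    f <- features[in_cat, , drop = FALSE]
    c(n = length(in_cat), bases = occupied_bases(f))
  }
  stats <- t(vapply(cat_order, stat_for, numeric(2)))
  data.frame(category = cat_order,
             n_elements = as.integer(stats[, "n"]),
             length_occupied = as.integer(stats[, "bases"]),
             pct_of_sequence = round(100 * stats[, "bases"] / total_bases, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Transcripts flagged as containing ribosomal RNA
#'
#' @param features data.frame from [parse_repeatmasker_out()].
#' @return unique transcript ids having at least one feature whose
#'   class/family contains the rRNA designation.
#' @export
flag_rrna <- function(features) {
  if (!nrow(features)) return(character())
  unique(features$transcript_id[grepl("rRNA", features$repeat_class_family)])
}
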