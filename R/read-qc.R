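## Read quality control: trim each read to its longest contiguous run of
## bases at or above a Phred threshold, drop reads that end up shorter than a
## minimum length, keep pair/singleton bookkeeping, and summarise read sets
## (Q20%, N%, GC%).

#' Read a FASTQ file (Sanger Phred+33) into a read set
#'
#' @param path FASTQ path.
#' @return a `read_set`: list with `id` (character), `seq` (character) and
#'   `qual` (list of integer Phred vectors), one entry per read.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(read_set(character(), character(), list()))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': record count not a multiple of 4", path))
  id <- sub("^@", "", lines[seq(1, length(lines), 4)])
  id <- sub("\\s.*$", "", id)
  seq <- toupper(lines[seq(2, length(lines), 4)])
  qual_chr <- lines[seq(4, length(lines), 4)]
  qual <- lapply(qual_chr, function(q) as.integer(charToRaw(q)) - 33L)
  bad <- which(vapply(qual, function(q) any(q < 0L | q > 93L), logical(1)))
  if (length(bad))
    stop(sprintf("FASTQ '%s' is not Sanger Phred+33 encoded (record %d)",
                 path, bad[1]))
  read_set(id, seq, qual)
}

read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  structure(list(id = id, seq = seq, qual = qual), class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set of %d reads", length(x)))
  if (length(x))
    cat(sprintf(" (length %d-%d bp)", min(nchar(x$seq)), max(nchar(x$seq))))
  cat("\n")
  invisible(x)
}

subset_read_set <- function(x, i) read_set(x$id[i], x$seq[i], x$qual[i])

#' Write a read set to FASTQ (Phred+33)
#'
#' @param reads a `read_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads)
  out <- character(4L * n)
  if (n) {
    out[seq(1, 4 * n, 4)] <- paste0("@", reads$id)
    out[seq(2, 4 * n, 4)] <- reads$seq
    out[seq(3, 4 * n, 4)] <- "+"
    out[seq(4, 4 * n, 4)] <- vapply(reads$qual, function(q)
      rawToChar(as.raw(q + 33L)), character(1))
  }
  writeLines(out, path)
  invisible(path)
}

## longest run of TRUE; returns c(start, length), leftmost on ties, c(0,0)
## when no TRUE
longest_true_run <- function(ok) {
  if (!any(ok)) return(c(0L, 0L))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]   # which.max is leftmost on ties
  c(starts[best], r$lengths[best])
}

#' Trim a read to its longest contiguous high-quality segment
#'
#' Keeps the longest run of consecutive bases whose Phred score is at or above
#' `phred_min` (default 13, i.e. error probability of about 0.05). Ties
#' between equally long runs are broken leftmost; a read with no qualifying
#' base becomes empty.
#'
#' @param seq read sequence (single string).
#' @param qual integer Phred vector, one score per base.
#' @param phred_min minimum Phred score a kept base must reach.
#' @return list with `seq` (possibly empty string) and `qual`.
#' @export
trim_read <- function(seq, qual, phred_min = 13L) {
  stopifnot(nchar(seq) == length(qual))
  run <- longest_true_run(qual >= phred_min)
  if (run[2] == 0L) return(list(seq = "", qual = integer()))
  list(seq = substr(seq, run[1], run[1] + run[2] - 1L),
       qual = qual[run[1]:(run[1] + run[2] - 1L)])
}

trim_read_set <- function(reads, phred_min = 13L) {
  trimmed <- mapply(trim_read, reads$seq, reads$qual,
                    MoreArgs = list(phred_min = phred_min), SIMPLIFY = FALSE,
                    USE.NAMES = FALSE)
  read_set(reads$id,
           vapply(trimmed, `[[`, character(1), "seq"),
           lapply(trimmed, `[[`, "qual"))
}

#' Trim read pairs and sort survivors into paired and singleton sets
#'
#' Both mates are trimmed with [trim_read()]; any read shorter than `min_len`
#' after trimming is removed. Pairs where both mates survive stay paired;
#' where exactly one survives, the survivor becomes a singleton; `n_removed`
#' counts individually removed reads.
#'
#' @param mate1,mate2 `read_set`s with mates aligned index-wise (same length).
#' @param min_len minimum post-trim read length kept (reads shorter than this
#'   are removed, so a 25 bp read survives the default).
#' @param phred_min passed to [trim_read()].
#' @return a `trimmed_read_set`: list with `paired` (list of `mate1`,
#'   `mate2`), `singletons` (a `read_set`) and `n_removed`.
#' @export
filter_and_sort <- function(mate1, mate2, min_len = 25L, phred_min = 13L) {
  if (length(mate1) != length(mate2))
    stop("mismatched pair files: mate record counts differ")
  t1 <- trim_read_set(mate1, phred_min)
  t2 <- trim_read_set(mate2, phred_min)
  ok1 <- nchar(t1$seq) >= min_len
  ok2 <- nchar(t2$seq) >= min_len
  both <- ok1 & ok2
  only1 <- ok1 & !ok2
  only2 <- ok2 & !ok1
  singles <- read_set(c(t1$id[only1], t2$id[only2]),
                      c(t1$seq[only1], t2$seq[only2]),
                      c(t1$qual[only1], t2$qual[only2]))
  structure(list(
    paired = list(mate1 = subset_read_set(t1, both),
                  mate2 = subset_read_set(t2, both)),
    singletons = singles,
    n_removed = sum(!ok1) + sum(!ok2)
  ), class = "trimmed_read_set")
}

#' @export
print.trimmed_read_set <- function(x, ...) {
  cat(sprintf("trimmed_read_set: %d read pairs, %d singletons, %d reads removed\n",
              length(x$paired$mate1), length(x$singletons), x$n_removed))
  invisible(x)
}

#' Summarise a read set (Q20%, N%, GC%, lengths)
#'
#' The Q20 percentage is the percent of reads whose mean per-base error
#' probability `10^(-Q/10)` is strictly below 1%. GC% is computed over non-N
#' bases only; the median length is the lower median for even counts.
#'
#' @param reads a `read_set`, or a list of `read_set`s which are pooled.
#' @return list with `total_reads`, `q20_pct`, `n_pct`, `gc_pct`, `mean_len`
#'   and `median_len`.
#' @export
read_set_summary <- function(reads) {
  if (!inherits(reads, "read_set")) {
    reads <- read_set(
      unlist(lapply(reads, `[[`, "id"), use.names = FALSE),
      unlist(lapply(reads, `[[`, "seq"), use.names = FALSE),
      do.call(c, lapply(reads, `[[`, "qual")))
  }
  n <- length(reads)
  if (n == 0L)
    return(list(total_reads = 0L, q20_pct = 0, n_pct = 0, gc_pct = 0,
                mean_len = 0, median_len = 0))
  lens <- nchar(reads$seq)
  mean_err <- vapply(reads$qual, function(q)
    if (length(q)) mean(10^(-q / 10)) else 1, numeric(1))
  all_bases <- paste(reads$seq, collapse = "")
  counts <- table(factor(strsplit(all_bases, "")[[1]],
                         levels = c("A", "C", "G", "T", "N")))
  non_n <- sum(counts[c("A", "C", "G", "T")])
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  list(
    total_reads = n,
    q20_pct = 100 * mean(mean_err < 0.01),
    n_pct = 100 * counts[["N"]] / sum(counts),
    gc_pct = if (non_n > 0) 100 * sum(counts[c("G", "C")]) / non_n else 0,
    mean_len = mean(lens),
    median_len = lower_median(lens)
  )
}
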