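#' Paired sequencing reads with per-base qualities
#'
#' Constructs a validated collection of read pairs. Sequences and qualities
#' are stored as plain character vectors (Phred+33 quality strings); adapter
#' detection is an upstream concern and enters only as a per-pair flag.
#'
#' @param id character vector of read-pair identifiers (unique).
#' @param seq1,qual1 mate-1 sequence and Phred+33 quality strings.
#' @param seq2,qual2 mate-2 sequence and quality strings.
#' @param adapter logical; `TRUE` when adapter sequence was detected in the
#'   pair by the upstream read processor.
#' @return A `read_pairs` object (a data frame with one row per pair).
#' @export
read_pairs <- function(id, seq1, qual1, seq2, qual2,
                       adapter = rep(FALSE, length(id))) {
  stopifnot(length(seq1) == length(id), length(seq2) == length(id),
            length(qual1) == length(id), length(qual2) == length(id),
            length(adapter) == length(id))
  bad <- nchar(seq1) != nchar(qual1) | nchar(seq2) != nchar(qual2)
  if (any(bad)) {
    stop("malformed read pair (sequence/quality length mismatch): ",
         paste(id[bad], collapse = ", "))
  }
  if (any(nchar(seq1) == 0L | nchar(seq2) == 0L)) {
    stop("empty read in pair(s): ",
         paste(id[nchar(seq1) == 0L | nchar(seq2) == 0L], collapse = ", "))
  }
  out <- data.frame(id = as.character(id),
                    seq1 = as.character(seq1), qual1 = as.character(qual1),
                    seq2 = as.character(seq2), qual2 = as.character(qual2),
                    adapter = as.logical(adapter),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Read paired FASTQ files
#'
#' Reads two parallel FASTQ files (4-line records, Phred+33). An adapter flag
#' set by an upstream detector is carried in the read description as the token
#' `adapter=1` after the read id.
#'
#' @param path1,path2 paths to the mate-1 and mate-2 FASTQ files.
#' @return A [read_pairs] object.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    stop("FASTQ files hold different numbers of reads: ",
         length(r1), " vs ", length(r2))
  }
  parse_desc <- function(nm) {
    tok <- strsplit(nm, " ", fixed = TRUE)
    list(id = vapply(tok, `[[`, "", 1L),
         adapter = vapply(tok, function(t) any(t == "adapter=1"), NA))
  }
  d1 <- parse_desc(names(r1))
  d2 <- parse_desc(names(r2))
  if (!identical(d1$id, d2$id)) stop("read ids differ between mates")
  qual <- function(r) as.character(S4Vectors::mcols(r)$qualities)
  read_pairs(id = d1$id,
             seq1 = as.character(r1), qual1 = qual(r1),
             seq2 = as.character(r2), qual2 = qual(r2),
             adapter = d1$adapter | d2$adapter)
}

#' Write paired FASTQ files
#'
#' @param pairs a [read_pairs] object.
#' @param path1,path2 output paths for mate 1 and mate 2.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  stopifnot(inherits(pairs, "read_pairs"))
  nm <- ifelse(pairs$adapter, paste0(pairs$id, " adapter=1"), pairs$id)
  wr <- function(seqs, quals, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(stats::setNames(seqs, nm)),
      Biostrings::PhredQuality(quals))
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  wr(pairs$seq1, pairs$qual1, path1)
  wr(pairs$seq2, pairs$qual2, path2)
  invisible(c(path1, path2))
}

phred_ints <- function(qual) {
  as(Biostrings::PhredQuality(qual), "IntegerList")
}

#' Filter read pairs on N content, base quality and adapter contamination
#'
#' A pair is removed when, in either mate, the number of ambiguous `N` bases
#' exceeds `max_n`, or the fraction of bases with Phred quality below
#' `lowq_threshold` exceeds `lowq_fraction`, or adapter sequence was flagged.
#' Both comparisons are strict, so a mate with exactly `max_n` Ns or exactly
#' `lowq_fraction` low-quality bases is kept. The removal set is the union of
#' the three rules; the report attributes each removed pair to the first rule
#' it trips, in the order N, low-quality, adapter.
#'
#' @param pairs a [read_pairs] object.
#' @param max_n maximum tolerated count of N bases per mate (default 3).
#' @param lowq_threshold Phred value under which a base counts as low quality
#'   (default 5).
#' @param lowq_fraction maximum tolerated fraction of low-quality bases per
#'   mate (default 0.20).
#' @return A list with elements `clean` (a [read_pairs] of retained pairs) and
#'   `report`, a one-row data frame with counts `n_input_pairs`,
#'   `n_removed_n`, `n_removed_lowq`, `n_removed_adapter`, `n_clean`.
#' @export
qc_filter_read_pairs <- function(pairs, max_n = 3L, lowq_threshold = 5L,
                                 lowq_fraction = 0.20) {
  stopifnot(inherits(pairs, "read_pairs"),
            max_n >= 0, lowq_threshold >= 0,
            lowq_fraction >= 0, lowq_fraction <= 1)
  n <- nrow(pairs)
  if (n == 0L) {
    report <- data.frame(n_input_pairs = 0L, n_removed_n = 0L,
                         n_removed_lowq = 0L, n_removed_adapter = 0L,
                         n_clean = 0L)
    return(list(clean = pairs, report = report))
  }
  n_count <- function(seqs) {
    as.vector(Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs), "N"))
  }
  lowq_frac <- function(quals) {
    q <- phred_ints(quals)
    vapply(q, function(v) mean(v < lowq_threshold), 0)
  }
  fail_n <- n_count(pairs$seq1) > max_n | n_count(pairs$seq2) > max_n
  fail_q <- lowq_frac(pairs$qual1) > lowq_fraction |
    lowq_frac(pairs$qual2) > lowq_fraction
  fail_a <- pairs$adapter
  removed <- fail_n | fail_q | fail_a
  report <- data.frame(
    n_input_pairs = n,
    n_removed_n = sum(fail_n),
    n_removed_lowq = sum(fail_q & !fail_n),
    n_removed_adapter = sum(fail_a & !fail_n & !fail_q),
    n_clean = sum(!removed))
  clean <- pairs[!removed, , drop = FALSE]
  rownames(clean) <- NULL
  class(clean) <- c("read_pairs", "data.frame")
  list(clean = clean, report = report)
}
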