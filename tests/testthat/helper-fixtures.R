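# Small in-code fixtures shared across test files.

make_expr <- function(values, genes = NULL, samples = NULL,
                      normalized = TRUE) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, normalized = normalized)
}

# A clean 150 bp read pair with uniform Phred-35 qualities.
clean_pair <- function(id = "p1", len = 150L) {
  q <- strrep(rawToChar(as.raw(33L + 35L)), len)
  read_pairs(id = id, seq1 = strrep("A", len), qual1 = q,
             seq2 = strrep("C", len), qual2 = q)
}

# Replace the first n quality characters of a mate with Phred `phred`.
with_lowq <- function(pairs, n, mate = 1L, phred = 4L) {
  col <- paste0("qual", mate)
  ch <- rawToChar(as.raw(33L + phred))
  pairs[[col]] <- paste0(strrep(ch, n),
                         substr(pairs[[col]], n + 1L, nchar(pairs[[col]])))
  pairs
}

# Replace the first n bases of a mate with N.
with_ns <- function(pairs, n, mate = 1L) {
  col <- paste0("seq", mate)
  pairs[[col]] <- paste0(strrep("N", n),
                         substr(pairs[[col]], n + 1L, nchar(pairs[[col]])))
  pairs
}

# One-trio pedigree.
trio_ped <- function(pb = "P1") {
  pedigree(family_id = rep("F1", 3L),
           sample_id = c(pb, paste0(pb, "_F"), paste0(pb, "_M")),
           father_id = c(paste0(pb, "_F"), "0", "0"),
           mother_id = c(paste0(pb, "_M"), "0", "0"),
           sex = c("male", "male", "female"),
           affected = c(TRUE, FALSE, FALSE))
}
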