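#' Gene-by-sample expression matrix
#'
#' A numeric matrix (genes in rows, samples in columns) with a normalization
#' flag. All entries must be non-negative and row/column names unique.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param normalized logical; whether library-size normalization has been
#'   applied.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!is.numeric(values)) stop("non-numeric expression values")
  if (any(!is.finite(values))) stop("non-finite expression values")
  if (any(values < 0)) stop("negative expression values")
  structure(values, normalized = isTRUE(normalized),
            class = c("expr_matrix", "matrix", "array"))
}

is_normalized <- function(m) isTRUE(attr(m, "normalized"))

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column `gene_id`, remaining columns one per sample; values are
#' non-negative counts or normalized quantities.
#'
#' @param path input TSV.
#' @param normalized whether the file already holds normalized values.
#' @return An [expr_matrix].
#' @export
read_expression_matrix <- function(path, normalized = FALSE) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression cell in ", path)
  rownames(vals) <- d[[1]]
  expr_matrix(vals, normalized = normalized)
}

#' Write an expression matrix to TSV
#' @param m an [expr_matrix].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(m, path) {
  d <- data.frame(gene_id = rownames(m), unclass(m)[, , drop = FALSE],
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-of-ratios library-size normalization
#'
#' Scales each sample by its median ratio to the per-gene geometric-mean
#' reference profile, computed over genes with nonzero geometric mean (the
#' standard size-factor estimator for count matrices).
#'
#' @param raw an [expr_matrix] of raw counts with at least two samples.
#' @return A normalized [expr_matrix]; size factors are attached as attribute
#'   `size_factors`.
#' @export
normalize_counts <- function(raw) {
  stopifnot(inherits(raw, "expr_matrix"))
  if (ncol(raw) < 2L) stop("normalization needs at least 2 samples")
  logg <- rowMeans(log(unclass(raw)))
  use <- is.finite(logg)
  if (!any(use)) {
    stop("no gene is nonzero in every sample; cannot estimate size factors")
  }
  sf <- apply(unclass(raw), 2L, function(col) {
    exp(stats::median(log(col[use]) - logg[use]))
  })
  out <- expr_matrix(sweep(unclass(raw), 2L, sf, "/"), normalized = TRUE)
  attr(out, "size_factors") <- sf
  out
}

#' Is a gene stably expressed in peripheral blood?
#'
#' A gene counts as blood-expressed when its cohort mean normalized expression
#' reaches `min_mean`. Genes absent from the matrix are not expressed (no
#' error).
#'
#' @param m a normalized [expr_matrix].
#' @param gene gene id(s).
#' @param min_mean expression threshold on the normalized scale (default 1).
#' @return Logical vector along `gene`.
#' @export
expressed_in_blood <- function(m, gene, min_mean = 1.0) {
  stopifnot(inherits(m, "expr_matrix"))
  idx <- match(gene, rownames(m))
  out <- rep(FALSE, length(gene))
  hit <- !is.na(idx)
  if (any(hit)) {
    out[hit] <- rowMeans(unclass(m)[idx[hit], , drop = FALSE]) >= min_mean
  }
  out
}

#' Per-gene cohort z-score of one patient
#'
#' Standardizes the patient's expression of a gene against the cohort: the
#' per-gene mean and population (n-denominator) standard deviation over all
#' samples. A gene constant across the cohort scores 0.
#'
#' @param m a normalized [expr_matrix].
#' @param gene gene id(s) present in `m`.
#' @param patient sample id.
#' @return Numeric vector of z-scores along `gene`.
#' @export
gene_zscore <- function(m, gene, patient) {
  x <- unclass(m)[gene, , drop = FALSE]
  mu <- rowMeans(x)
  sdp <- sqrt(rowMeans((x - mu)^2))
  z <- (x[, patient] - mu) / sdp
  z[sdp == 0] <- 0
  unname(z)
}

#' Per-gene log2 fold change of one patient against the cohort mean
#'
#' `log2((x + pseudocount) / (cohort mean + pseudocount))`; the pseudocount
#' guards zero expression and is negligible at typical normalized magnitudes.
#'
#' @param m a normalized [expr_matrix].
#' @param gene gene id(s) present in `m`.
#' @param patient sample id.
#' @param pseudocount additive constant on the normalized scale (default 1).
#' @return Numeric vector of log2 fold changes along `gene`.
#' @export
gene_log2fc <- function(m, gene, patient, pseudocount = 1.0) {
  x <- unclass(m)[gene, , drop = FALSE]
  mu <- rowMeans(x)
  unname(log2((x[, patient] + pseudocount) / (mu + pseudocount)))
}
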