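with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Expression-dosage validation of one CNV
#'
#' Tests whether a candidate CNV leaves the expected dosage footprint in the
#' carrier's blood transcriptome. Genes overlapping the CNV span by at least
#' one bp (or fully contained, see `membership`) form the in-CNV set; the
#' statistics are the means, over blood-expressed in-CNV genes, of the
#' per-gene cohort z-score and log2 fold change of the carrier. Three
#' background summaries accompany them: the same means over all expressed
#' genes on the CNV's chromosome (`zscore_chr`, `log2fc_chr`) and over
#' `n_random_sets` independently drawn sets of expressed out-CNV genes on
#' that chromosome, each of the same size as the expressed in-CNV set
#' (negative controls). A CNV whose genes are all silent in blood is
#' `not_expressed` and carries no statistics.
#'
#' @param m a normalized [expr_matrix] containing the CNV carrier.
#' @param cnv one-row [cnv_calls] table (the carrier's CNV).
#' @param genes a [gene_models] table covering the CNV's chromosome.
#' @param n_random_sets number of out-CNV control sets (default 3).
#' @param seed integer seed for drawing the control sets.
#' @param min_mean blood-expression threshold passed to
#'   [expressed_in_blood()].
#' @param membership `"overlap"` (>= 1 bp, default) or `"within"` (gene fully
#'   inside the CNV).
#' @return A list of class `dosage_result`: `sample_id`, `chrom`, `start`,
#'   `end`, `cnv_type`, `gene_in_cnv`, `rna_in_cnv`, `status`
#'   (`"evaluable"`/`"not_expressed"`) and, when evaluable, `zscore_chr`,
#'   `zscore_cnv`, `zscore_random` (vector), `log2fc_chr`, `log2fc_cnv`,
#'   `log2fc_random` (vector).
#' @export
cnv_dosage_validation <- function(m, cnv, genes, n_random_sets = 3L,
                                  seed = 1L, min_mean = 1.0,
                                  membership = c("overlap", "within")) {
  stopifnot(inherits(m, "expr_matrix"), nrow(cnv) == 1L)
  membership <- match.arg(membership)
  if (!cnv$sample_id %in% colnames(m)) {
    stop("CNV carrier ", cnv$sample_id, " absent from expression matrix")
  }
  chr_genes <- genes[genes$chrom == cnv$chrom, , drop = FALSE]
  hits <- GenomicRanges::findOverlaps(
    gene_ranges(chr_genes),
    GenomicRanges::GRanges(cnv$chrom, IRanges::IRanges(cnv$start, cnv$end)),
    type = if (membership == "overlap") "any" else "within")
  in_cnv <- chr_genes$gene_id[S4Vectors::queryHits(hits)]
  in_matrix <- intersect(in_cnv, rownames(m))
  expr_in <- in_matrix[expressed_in_blood(m, in_matrix, min_mean)]
  out <- list(sample_id = cnv$sample_id, chrom = cnv$chrom,
              start = cnv$start, end = cnv$end, cnv_type = cnv$cnv_type,
              gene_in_cnv = length(in_cnv), rna_in_cnv = length(expr_in))
  if (length(expr_in) == 0L) {
    out$status <- "not_expressed"
    class(out) <- "dosage_result"
    return(out)
  }
  chr_all <- intersect(chr_genes$gene_id, rownames(m))
  expr_chr <- chr_all[expressed_in_blood(m, chr_all, min_mean)]
  pool <- setdiff(expr_chr, in_cnv)
  k <- length(expr_in)
  if (length(pool) < k) {
    stop("only ", length(pool), " expressed out-CNV genes on ", cnv$chrom,
         " but ", k, " needed per control set; enlarge the gene universe")
  }
  pt <- cnv$sample_id
  set_stats <- function(gs) {
    c(z = mean(gene_zscore(m, gs, pt)), fc = mean(gene_log2fc(m, gs, pt)))
  }
  rand <- with_local_seed(seed, {
    lapply(seq_len(n_random_sets), function(i) sample(pool, k))
  })
  rs <- vapply(rand, set_stats, c(z = 0, fc = 0))
  s_cnv <- set_stats(expr_in)
  s_chr <- set_stats(expr_chr)
  out$status <- "evaluable"
  out$zscore_chr <- unname(s_chr["z"])
  out$zscore_cnv <- unname(s_cnv["z"])
  out$zscore_random <- unname(rs["z", ])
  out$log2fc_chr <- unname(s_chr["fc"])
  out$log2fc_cnv <- unname(s_cnv["fc"])
  out$log2fc_random <- unname(rs["fc", ])
  class(out) <- "dosage_result"
  out
}

#' Does a dosage result point in the direction the CNV type predicts?
#'
#' A duplication is consistent when both its z-score and log2 fold change
#' exceed the maxima of all random control sets; a deletion when both fall
#' below the minima.
#'
#' @param r a `dosage_result` from [cnv_dosage_validation()].
#' @param cnv_type `"duplication"` or `"deletion"`; defaults to the type
#'   recorded in `r`.
#' @return `TRUE`/`FALSE`.
#' @export
direction_consistent <- function(r, cnv_type = r$cnv_type) {
  stopifnot(inherits(r, "dosage_result"))
  if (r$status != "evaluable") {
    stop("dosage result is not evaluable (no in-CNV gene expressed in blood)")
  }
  if (cnv_type == "duplication") {
    r$zscore_cnv > max(r$zscore_random) && r$log2fc_cnv > max(r$log2fc_random)
  } else {
    r$zscore_cnv < min(r$zscore_random) && r$log2fc_cnv < min(r$log2fc_random)
  }
}

#' Flatten dosage results into a report table
#'
#' One row per CNV in the layout of the cohort's CNV-validation table:
#' counts, chromosome background, CNV set, and one column pair per random
#' control set. Non-evaluable rows carry `NA` statistics.
#'
#' @param results list of `dosage_result` objects.
#' @return A data frame.
#' @export
dosage_result_table <- function(results) {
  k <- max(c(1L, vapply(results, function(r)
    length(if (is.null(r$zscore_random)) numeric() else r$zscore_random), 0L)))
  rows <- lapply(results, function(r) {
    base <- data.frame(sample_id = r$sample_id, chrom = r$chrom,
                       start = r$start, end = r$end, cnv_type = r$cnv_type,
                       gene_in_cnv = r$gene_in_cnv, rna_in_cnv = r$rna_in_cnv,
                       status = r$status, stringsAsFactors = FALSE)
    ev <- r$status == "evaluable"
    base$zscore_chr <- if (ev) r$zscore_chr else NA_real_
    base$zscore_cnv <- if (ev) r$zscore_cnv else NA_real_
    for (i in seq_len(k)) {
      base[[paste0("zscore_random", i)]] <-
        if (ev) r$zscore_random[i] else NA_real_
    }
    base$log2fc_chr <- if (ev) r$log2fc_chr else NA_real_
    base$log2fc_cnv <- if (ev) r$log2fc_cnv else NA_real_
    for (i in seq_len(k)) {
      base[[paste0("log2fc_random", i)]] <-
        if (ev) r$log2fc_random[i] else NA_real_
    }
    base
  })
  do.call(rbind, rows)
}

#' Expression check of a truncating-variant gene
#'
#' Compares the patient's expression of the mutant gene with the cohort mean
#' (over all samples, the patient included, unless `include_patient = FALSE`).
#' Nonsense-mediated decay predicts a reduction for truncating variants.
#'
#' @param m a normalized [expr_matrix].
#' @param gene gene id.
#' @param patient sample id present in `m`.
#' @param min_mean blood-expression threshold.
#' @param include_patient include the index patient in the cohort mean
#'   (default `TRUE`).
#' @return A one-row data frame: `gene`, `expressed_in_blood`,
#'   `patient_level`, `cohort_mean_level`, `reduced`.
#' @export
snv_expression_check <- function(m, gene, patient, min_mean = 1.0,
                                 include_patient = TRUE) {
  stopifnot(inherits(m, "expr_matrix"), patient %in% colnames(m))
  if (!expressed_in_blood(m, gene, min_mean)) {
    return(data.frame(gene = gene, expressed_in_blood = FALSE,
                      patient_level = NA_real_, cohort_mean_level = NA_real_,
                      reduced = NA, stringsAsFactors = FALSE))
  }
  x <- unclass(m)[gene, ]
  lvl <- unname(x[patient])
  ctrl <- if (include_patient) mean(x) else mean(x[names(x) != patient])
  data.frame(gene = gene, expressed_in_blood = TRUE, patient_level = lvl,
             cohort_mean_level = ctrl, reduced = lvl < ctrl,
             stringsAsFactors = FALSE)
}
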