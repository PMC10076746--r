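#' Construct a qPCR plate
#'
#' Long-format triplicate Cq measurements for target and reference assays
#' across samples, with one calibrator (normal control) sample per plate.
#'
#' @param sample_id,target_gene,role,is_calibrator,replicate,cq,efficiency
#'   parallel vectors: `role` is `"target"` or `"reference"`; `efficiency` is
#'   the per-cycle amplification factor in (1, 2], shared within a gene
#'   (`NA` means the standard assumption of perfect doubling, E = 2).
#' @return A `qpcr_plate` data frame.
#' @export
qpcr_plate <- function(sample_id, target_gene, role, is_calibrator,
                       replicate, cq, efficiency = rep(NA_real_,
                                                       length(sample_id))) {
  out <- data.frame(sample_id = as.character(sample_id),
                    target_gene = as.character(target_gene),
                    role = as.character(role),
                    is_calibrator = as.logical(is_calibrator),
                    replicate = as.integer(replicate), cq = as.numeric(cq),
                    efficiency = as.numeric(efficiency),
                    stringsAsFactors = FALSE)
  if (any(!out$role %in% c("target", "reference"))) {
    stop("role must be 'target' or 'reference'")
  }
  if (any(!is.na(out$efficiency) &
          (out$efficiency <= 1 | out$efficiency > 2))) {
    stop("efficiency must lie in (1, 2]")
  }
  cal <- unique(out$sample_id[out$is_calibrator])
  if (length(cal) != 1L) {
    stop("plate must have exactly one calibrator sample, found ",
         length(cal))
  }
  eff_n <- tapply(out$efficiency, out$target_gene,
                  function(e) length(unique(e[!is.na(e)])))
  if (any(eff_n > 1L)) {
    stop("efficiency differs within gene(s): ",
         paste(names(eff_n)[eff_n > 1L], collapse = ", "))
  }
  reps <- table(paste(out$sample_id, out$target_gene))
  if (any(reps < 2L)) {
    stop("replicate group(s) with fewer than 2 wells: ",
         paste(names(reps)[reps < 2L], collapse = ", "))
  }
  class(out) <- c("qpcr_plate", "data.frame")
  out
}

#' Read a qPCR plate from CSV
#'
#' Columns: `sample_id`, `target_gene`, `role` (target/reference),
#' `is_calibrator` (0/1), `replicate`, `cq`, `efficiency`.
#'
#' @param path input CSV.
#' @return A [qpcr_plate].
#' @export
read_qpcr_plate <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  qpcr_plate(d$sample_id, d$target_gene, d$role, d$is_calibrator == 1,
             d$replicate, d$cq,
             if ("efficiency" %in% names(d)) d$efficiency else
               rep(NA_real_, nrow(d)))
}

#' Write a qPCR plate to CSV
#' @param x a [qpcr_plate].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_qpcr_plate <- function(x, path) {
  d <- as.data.frame(x)
  d$is_calibrator <- as.integer(d$is_calibrator)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average technical replicates of a Cq group
#'
#' Arithmetic mean of the replicate Cq values. When three or more replicates
#' span a range wider than `max_range` cycles, the single value farthest from
#' the median is discarded first (a common plate-QC convention).
#'
#' @param cqs numeric vector of at least two finite Cq values.
#' @param max_range tolerated within-group range in cycles (default 0.5).
#' @return The mean Cq.
#' @export
aggregate_replicates <- function(cqs, max_range = 0.5) {
  if (length(cqs) < 2L || any(!is.finite(cqs))) {
    stop("need >= 2 finite Cq replicates")
  }
  if (length(cqs) >= 3L && diff(range(cqs)) > max_range) {
    cqs <- cqs[-which.max(abs(cqs - stats::median(cqs)))]
  }
  mean(cqs)
}

#' Efficiency-corrected relative quantity
#'
#' `RQ = E^(Cq_calibrator - Cq_sample)`: one cycle earlier than the
#' calibrator means E-fold more template.
#'
#' @param cq_sample,cq_calibrator mean Cq values.
#' @param efficiency amplification factor per cycle in (1, 2] (default 2).
#' @return The relative quantity (positive).
#' @export
relative_quantity <- function(cq_sample, cq_calibrator, efficiency = 2) {
  if (!is.finite(cq_sample) || !is.finite(cq_calibrator)) {
    stop("non-finite Cq")
  }
  stopifnot(efficiency > 1, efficiency <= 2)
  efficiency^(cq_calibrator - cq_sample)
}

#' Reference-gene normalized relative quantity
#'
#' `NRQ = RQ_target / RQ_reference`. Because both quantities are expressed
#' relative to the calibrator, the calibrator's NRQ is 1 by construction
#' (the normal control is set to 1).
#'
#' @param rq_target,rq_reference positive relative quantities of the target
#'   and reference assays for the same sample.
#' @return The normalized relative quantity.
#' @export
normalized_relative_quantity <- function(rq_target, rq_reference) {
  if (!is.finite(rq_target) || rq_target <= 0 ||
      !is.finite(rq_reference) || rq_reference <= 0) {
    stop("relative quantities must be positive")
  }
  rq_target / rq_reference
}

#' Classify copy number from an NRQ
#'
#' Thresholds default to the midpoints between the diploid expectation (1)
#' and the heterozygous deletion/duplication expectations (0.5 and 1.5).
#'
#' @param nrq positive normalized relative quantity (vectorized).
#' @param del_max NRQ at or below which a deletion is called (default 0.75).
#' @param dup_min NRQ at or above which a duplication is called
#'   (default 1.25).
#' @return Character vector: `"deletion"`, `"normal"` or `"duplication"`.
#' @export
call_copy_number <- function(nrq, del_max = 0.75, dup_min = 1.25) {
  stopifnot(all(nrq > 0))
  ifelse(nrq <= del_max, "deletion",
         ifelse(nrq >= dup_min, "duplication", "normal"))
}

#' Full qBase-style quantification of a plate
#'
#' Aggregates replicates, computes efficiency-corrected relative quantities
#' against the calibrator sample, normalizes targets by the reference gene,
#' and calls copy number.
#'
#' @param plate a [qpcr_plate].
#' @param del_max,dup_min copy-number call thresholds (see
#'   [call_copy_number()]).
#' @return A data frame with one row per (sample, target gene):
#'   `sample_id`, `target_gene`, `delta_cq` (calibrator minus sample mean Cq
#'   of the target assay), `nrq`, `call`.
#' @export
quantify_plate <- function(plate, del_max = 0.75, dup_min = 1.25) {
  stopifnot(inherits(plate, "qpcr_plate"))
  cal <- unique(plate$sample_id[plate$is_calibrator])
  grp <- unique(plate[c("sample_id", "target_gene", "role")])
  grp$mean_cq <- mapply(function(s, g) {
    aggregate_replicates(plate$cq[plate$sample_id == s &
                                    plate$target_gene == g])
  }, grp$sample_id, grp$target_gene)
  eff <- vapply(unique(plate$target_gene), function(g) {
    e <- plate$efficiency[plate$target_gene == g]
    e <- unique(e[!is.na(e)])
    if (length(e)) e else 2
  }, 0)
  cal_cq <- function(g) grp$mean_cq[grp$sample_id == cal &
                                      grp$target_gene == g]
  grp$rq <- mapply(function(s, g, cq) {
    relative_quantity(cq, cal_cq(g), eff[[g]])
  }, grp$sample_id, grp$target_gene, grp$mean_cq)
  targets <- grp[grp$role == "target", , drop = FALSE]
  refs <- grp[grp$role == "reference", , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    s <- targets$sample_id[i]
    rq_ref <- refs$rq[refs$sample_id == s]
    if (length(rq_ref) != 1L) {
      stop("sample ", s, " needs exactly one reference assay")
    }
    data.frame(sample_id = s, target_gene = targets$target_gene[i],
               delta_cq = cal_cq(targets$target_gene[i]) - targets$mean_cq[i],
               nrq = normalized_relative_quantity(targets$rq[i], rq_ref),
               stringsAsFactors = FALSE)
  }))
  out$call <- call_copy_number(out$nrq, del_max, dup_min)
  rownames(out) <- NULL
  out
}
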