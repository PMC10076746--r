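#' Percentage with half-up rounding to one decimal
#'
#' @param k numerator count, `0 <= k <= n`.
#' @param n denominator count, positive.
#' @return `100 * k / n` rounded half-up to one decimal place.
#' @export
percent <- function(k, n) {
  if (any(n <= 0)) stop("denominator must be positive")
  stopifnot(all(k >= 0), all(k <= n))
  floor(1000 * k / n + 0.5) / 10
}

#' Cohort-level diagnostic summary
#'
#' Tallies diagnostic yields from triage findings: SNV-positive and
#' CNV-positive probands, distinct positives, probands whose every finding
#' is de novo, CNV breakdowns by type and origin, per-category rates
#' (percent of the cohort, one decimal) and the proband sex ratio.
#'
#' @param findings a `findings` table from [triage()].
#' @param sex named character vector (or [pedigree]) giving `"male"` /
#'   `"female"` for every proband in the cohort; its length defines the
#'   cohort size.
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(findings, sex) {
  if (inherits(sex, "pedigree")) {
    ped <- sex
    pb <- probands(ped)
    sex <- stats::setNames(ped$sex[match(pb, ped$sample_id)], pb)
  }
  n_total <- length(sex)
  if (n_total == 0L) stop("empty cohort")
  pos <- unique(findings$sample_id)
  miss <- setdiff(pos, names(sex))
  if (length(miss)) {
    stop("sex metadata missing for proband(s): ",
         paste(miss, collapse = ", "))
  }
  snv_pos <- unique(findings$sample_id[findings$variant_type == "snv"])
  cnv_pos <- unique(findings$sample_id[findings$variant_type == "cnv"])
  all_dn <- vapply(pos, function(p) {
    all(findings$origin[findings$sample_id == p] == "de_novo")
  }, NA)
  cnv_f <- findings[findings$variant_type == "cnv", , drop = FALSE]
  n_male <- sum(sex == "male")
  n_female <- sum(sex == "female")
  out <- list(
    n_total = n_total, n_male = n_male, n_female = n_female,
    male_female_ratio = if (n_female > 0) round(n_male / n_female, 2) else
      NA_real_,
    n_snv_pos = length(snv_pos), n_cnv_pos = length(cnv_pos),
    n_pos = length(pos), n_de_novo_pos = sum(all_dn),
    rate_snv = percent(length(snv_pos), n_total),
    rate_cnv = percent(length(cnv_pos), n_total),
    rate_total = percent(length(pos), n_total),
    rate_de_novo = percent(sum(all_dn), n_total),
    cnv_n_dup = sum(cnv_f$cnv_type == "duplication"),
    cnv_n_del = sum(cnv_f$cnv_type == "deletion"),
    cnv_n_de_novo = length(unique(cnv_f$sample_id[cnv_f$origin ==
                                                    "de_novo"])),
    cnv_n_inherited = length(unique(cnv_f$sample_id[cnv_f$origin %in%
                                                      c("paternal",
                                                        "maternal",
                                                        "inherited_both")])))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d probands (%d male / %d female, ratio %.2f : 1)\n",
              x$n_total, x$n_male, x$n_female, x$male_female_ratio))
  cat(sprintf("SNV-positive: %d (%.1f%%)\n", x$n_snv_pos, x$rate_snv))
  cat(sprintf("CNV-positive: %d (%.1f%%)  [%d dup / %d del; %d de novo / %d inherited]\n",
              x$n_cnv_pos, x$rate_cnv, x$cnv_n_dup, x$cnv_n_del,
              x$cnv_n_de_novo, x$cnv_n_inherited))
  cat(sprintf("Total positive: %d (%.1f%%); de novo positive: %d (%.1f%%)\n",
              x$n_pos, x$rate_total, x$n_de_novo_pos, x$rate_de_novo))
  invisible(x)
}

#' Count patients whose features match every keyword group
#'
#' Case-insensitive substring matching on free-text symptom strings: a
#' patient counts when each keyword group contributes at least one matching
#' keyword. Patients flagged lost to follow-up are excluded before matching.
#'
#' @param features named character vector of per-patient feature strings.
#' @param groups list of character vectors of keywords; the default groups
#'   capture the intellectual-disability and language-delay comorbidity pair.
#' @param lost_pattern regular expression flagging lost-to-follow-up
#'   patients.
#' @return Integer count of matching patients.
#' @export
comorbidity_tally <- function(features,
                              groups = list("intellectual", "language"),
                              lost_pattern = "lost.{0,4}follow[ -]?up") {
  if (any(!vapply(groups, length, 0L))) stop("empty keyword group")
  keep <- !grepl(lost_pattern, features, ignore.case = TRUE)
  features <- features[keep]
  hits <- vapply(features, function(f) {
    all(vapply(groups, function(g) {
      any(vapply(g, function(k) grepl(k, f, ignore.case = TRUE,
                                      fixed = FALSE), NA))
    }, NA))
  }, NA)
  sum(hits)
}
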