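#' Path to a bundled demonstration file
#' @param file file name under the package's `extdata/demo` directory.
#' @return Absolute path.
#' @export
demo_path <- function(file) {
  p <- system.file("extdata", "demo", file, package = "triodx",
                   mustWork = TRUE)
  p
}

#' Bundled demonstration cohort
#'
#' A transcription of the diagnosed findings of a published 354-child ASD
#' trio cohort: 10 probands with de novo protein-truncating SNVs, 9 with
#' known-region CNVs (5 de novo, 4 inherited), their clinical feature
#' strings, the matching known-region catalog and ASD gene list, and the
#' cohort sex composition (279 males, 75 females; sexes of the 335
#' undiagnosed probands are filled to those totals). Trio genotypes and
#' parental CNV carrier calls are reconstructed from each finding's reported
#' inheritance origin, so the full triage machinery can run on the set.
#'
#' @return A list: `ped` (19 trios), `snvs` (`snv_calls`), `cnvs`
#'   ([cnv_calls] incl. carrier parents), `genes_of_interest`
#'   ([gene_list]), `catalog` (`region_catalog`), `features` (named
#'   character), `sex` (named character, length 354).
#' @export
demo_cohort <- function() {
  snv_t <- utils::read.table(demo_path("snv_table.tsv"), sep = "\t",
                             header = TRUE, quote = "",
                             stringsAsFactors = FALSE)
  cnv_t <- utils::read.table(demo_path("cnv_table.tsv"), sep = "\t",
                             header = TRUE, quote = "",
                             stringsAsFactors = FALSE)
  feat <- utils::read.table(demo_path("clinical_features.tsv"), sep = "\t",
                            header = TRUE, quote = "", comment.char = "",
                            stringsAsFactors = FALSE)
  gl <- read_gene_list(demo_path("gene_list.tsv"))
  cat <- read_region_catalog(demo_path("region_catalog.tsv"))

  pb <- sort(unique(c(snv_t$sample_id, cnv_t$sample_id)))
  sex_pb <- feat$sex[match(pb, feat$sample_id)]
  ped <- pedigree(
    family_id = rep(paste0("FAM_", pb), 3L),
    sample_id = c(pb, paste0(pb, "_F"), paste0(pb, "_M")),
    father_id = c(paste0(pb, "_F"), rep("0", 2L * length(pb))),
    mother_id = c(paste0(pb, "_M"), rep("0", 2L * length(pb))),
    sex = c(sex_pb, rep("male", length(pb)), rep("female", length(pb))),
    affected = c(rep(TRUE, length(pb)), rep(FALSE, 2L * length(pb))))

  gt_from_origin <- function(origin) {
    data.frame(gt_proband = "het",
               gt_father = ifelse(origin == "paternal", "het", "hom_ref"),
               gt_mother = ifelse(origin == "maternal", "het", "hom_ref"),
               stringsAsFactors = FALSE)
  }
  snvs <- cbind(
    data.frame(sample_id = snv_t$sample_id, chrom = NA_character_,
               pos = NA_integer_,
               variant_id = paste0(snv_t$gene, ":", snv_t$hgvs_c),
               gene = snv_t$gene, consequence = snv_t$consequence,
               hgvs_c = snv_t$hgvs_c, hgvs_p = snv_t$hgvs_p,
               stringsAsFactors = FALSE),
    gt_from_origin(snv_t$origin))
  class(snvs) <- c("snv_calls", "data.frame")

  par_rows <- cnv_t[cnv_t$origin %in% c("paternal", "maternal"), ,
                    drop = FALSE]
  par_ids <- ifelse(par_rows$origin == "paternal",
                    paste0(par_rows$sample_id, "_F"),
                    paste0(par_rows$sample_id, "_M"))
  cnvs <- cnv_calls(
    sample_id = c(cnv_t$sample_id, par_ids),
    chrom = c(cnv_t$chrom, par_rows$chrom),
    start = c(cnv_t$start, par_rows$start),
    end = c(cnv_t$end, par_rows$end),
    cnv_type = c(cnv_t$cnv_type, par_rows$cnv_type))

  n_total <- 354L
  n_male <- 279L
  known_sex <- stats::setNames(feat$sex, feat$sample_id)
  n_fill <- n_total - length(known_sex)
  fill_male <- n_male - sum(known_sex == "male")
  fill <- stats::setNames(
    c(rep("male", fill_male), rep("female", n_fill - fill_male)),
    sprintf("UNDX%04d", seq_len(n_fill)))

  list(ped = ped, snvs = snvs, cnvs = cnvs, genes_of_interest = gl,
       catalog = cat,
       features = stats::setNames(feat$features, feat$sample_id),
       sex = c(known_sex, fill))
}

#' Published CNV dosage-validation rows as `dosage_result` objects
#'
#' Reconstructs the cohort's CNV RNA-seq validation table (in-CNV gene
#' counts, chromosome/CNV/random-set z-scores and log2 fold changes) as
#' `dosage_result` objects so direction consistency can be checked on the
#' reported values.
#'
#' @return A named list of `dosage_result` objects keyed by proband id.
#' @export
demo_dosage_results <- function() {
  d <- utils::read.table(demo_path("cnv_rnaseq_table.tsv"), sep = "\t",
                         header = TRUE, quote = "", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i) {
    r <- list(sample_id = d$sample_id[i], chrom = d$band[i],
              start = NA_integer_, end = NA_integer_,
              cnv_type = d$cnv_type[i], gene_in_cnv = d$gene_in_cnv[i],
              rna_in_cnv = d$rna_in_cnv[i])
    if (d$rna_in_cnv[i] == 0L) {
      r$status <- "not_expressed"
    } else {
      r$status <- "evaluable"
      r$zscore_chr <- d$zscore_chr[i]
      r$zscore_cnv <- d$zscore_cnv[i]
      r$zscore_random <- c(d$zscore_random1[i], d$zscore_random2[i],
                           d$zscore_random3[i])
      r$log2fc_chr <- d$log2fc_chr[i]
      r$log2fc_cnv <- d$log2fc_cnv[i]
      r$log2fc_random <- c(d$log2fc_random1[i], d$log2fc_random2[i],
                           d$log2fc_random3[i])
    }
    class(r) <- "dosage_result"
    r
  })
  stats::setNames(out, d$sample_id)
}
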