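#' @importFrom utils read.table write.table read.csv write.csv
NULL

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")
ORIGIN_LEVELS <- c("de_novo", "paternal", "maternal", "inherited_both",
                   "ambiguous")
CONSEQUENCE_LEVELS <- c("nonsense", "frameshift", "splice_donor",
                        "splice_acceptor", "missense", "synonymous", "other")

# --- gene models ------------------------------------------------------------

#' Construct a gene model table
#'
#' Internal coordinates are 1-based and inclusive on both ends throughout the
#' package; conversion from BED happens only at the file boundary.
#'
#' @param gene_id,chrom,start,end,strand parallel vectors describing one gene
#'   per element.
#' @return A `gene_models` data frame.
#' @export
gene_models <- function(gene_id, chrom, start, end,
                        strand = rep("+", length(gene_id))) {
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand), stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  }
  if (any(out$end < out$start)) {
    stop("gene model with end < start: ",
         paste(out$gene_id[out$end < out$start], collapse = ", "))
  }
  if (any(!nzchar(out$chrom))) stop("empty chromosome name")
  if (any(!out$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Read gene models from BED or tabular files
#'
#' BED input (0-based, half-open) is converted to the package's 1-based
#' inclusive convention; `tsv` input (columns `gene_id`, `chrom`, `start`,
#' `end`, `strand`, with header) is taken as already 1-based inclusive.
#'
#' @param path input file.
#' @param format `"bed"`, `"tsv"`, or `"auto"` (by file extension).
#' @return A [gene_models] data frame.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    d <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand")[1:6],
                    fill = TRUE)
    bad <- which(d$end < d$start)
    if (length(bad)) {
      stop("BED interval with end < start at line ", bad[1])
    }
    gene_models(gene_id = d$name, chrom = d$chrom,
                start = d$start + 1L, end = d$end,
                strand = ifelse(is.na(d$strand) | !nzchar(d$strand),
                                "+", d$strand))
  } else {
    d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    gene_models(d$gene_id, d$chrom, d$start, d$end, d$strand)
  }
}

#' Write gene models
#'
#' @param x a [gene_models] table.
#' @param path output file.
#' @param format `"bed"` (coordinates converted back to 0-based half-open) or
#'   `"tsv"` (1-based inclusive, with header).
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(x, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    d <- data.frame(x$chrom, x$start - 1L, x$end, x$gene_id, 0L, x$strand)
    write.table(d, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

gene_ranges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         gene_id = genes$gene_id)
}

# --- CNV calls --------------------------------------------------------------

#' Construct a CNV call table
#'
#' @param sample_id,chrom,start,end,cnv_type parallel vectors; coordinates are
#'   1-based inclusive, `cnv_type` is `"duplication"` or `"deletion"`.
#' @param origin optional inheritance origin (set by [cnv_origin()]).
#' @return A `cnv_calls` data frame with a `size` column in bp.
#' @export
cnv_calls <- function(sample_id, chrom, start, end, cnv_type,
                      origin = rep(NA_character_, length(sample_id))) {
  out <- data.frame(sample_id = as.character(sample_id),
                    chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    cnv_type = as.character(cnv_type),
                    origin = as.character(origin), stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) {
    stop("CNV with end <= start for sample ",
         paste(out$sample_id[out$end <= out$start], collapse = ", "))
  }
  if (any(!out$cnv_type %in% c("duplication", "deletion"))) {
    stop("cnv_type must be 'duplication' or 'deletion'")
  }
  out$size <- out$end - out$start + 1L
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Read CNV calls from a BED-like TSV
#'
#' Expects a header line with columns `sample_id`, `chrom`, `start`, `end`,
#' `cnv_type` and optionally `origin`; coordinates 1-based inclusive.
#'
#' @param path input TSV.
#' @return A [cnv_calls] data frame.
#' @export
read_cnv_calls <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  cnv_calls(d$sample_id, d$chrom, d$start, d$end, d$cnv_type,
            origin = if ("origin" %in% names(d)) d$origin else
              rep(NA_character_, nrow(d)))
}

#' Write CNV calls to TSV
#' @param x a [cnv_calls] table.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_cnv_calls <- function(x, path) {
  write.table(as.data.frame(x)[c("sample_id", "chrom", "start", "end",
                                 "cnv_type", "origin")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cnv_ranges <- function(cnvs) {
  GenomicRanges::GRanges(cnvs$chrom, IRanges::IRanges(cnvs$start, cnvs$end))
}

# --- pedigree ---------------------------------------------------------------

#' Read a 6-column PED file
#'
#' Columns: family id, sample id, father id, mother id, sex (1 = male,
#' 2 = female, 0 = unknown), phenotype (2 = affected). Founders use `0` for
#' missing parent ids.
#'
#' @param path PED file (whitespace separated, no header).
#' @return A `pedigree` data frame with columns `family_id`, `sample_id`,
#'   `father_id`, `mother_id`, `sex` (`"male"`/`"female"`/`"unknown"`),
#'   `affected` (logical).
#' @export
read_pedigree <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("family_id", "sample_id", "father_id",
                                "mother_id", "sex", "phenotype"),
                  colClasses = c(rep("character", 4), "integer", "integer"))
  pedigree(d$family_id, d$sample_id, d$father_id, d$mother_id,
           sex = c("unknown", "male", "female")[d$sex + 1L],
           affected = d$phenotype == 2L)
}

#' Construct a pedigree table
#' @param family_id,sample_id,father_id,mother_id,sex,affected parallel
#'   vectors; `sex` one of `"male"`, `"female"`, `"unknown"`.
#' @return A `pedigree` data frame.
#' @export
pedigree <- function(family_id, sample_id, father_id, mother_id, sex,
                     affected) {
  out <- data.frame(family_id = as.character(family_id),
                    sample_id = as.character(sample_id),
                    father_id = as.character(father_id),
                    mother_id = as.character(mother_id),
                    sex = as.character(sex), affected = as.logical(affected),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample_id in pedigree")
  if (any(!out$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be male/female/unknown")
  }
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Write a pedigree as a 6-column PED file
#' @param x a [pedigree] table.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(x, path) {
  d <- data.frame(x$family_id, x$sample_id, x$father_id, x$mother_id,
                  match(x$sex, c("unknown", "male", "female")) - 1L,
                  ifelse(x$affected, 2L, 1L))
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Probands of a pedigree
#'
#' Samples with both parents present in the pedigree.
#' @param ped a [pedigree] table.
#' @return Character vector of proband sample ids.
#' @export
probands <- function(ped) {
  ped$sample_id[ped$father_id %in% ped$sample_id &
                  ped$mother_id %in% ped$sample_id]
}

# --- SNV calls (VCF) --------------------------------------------------------

map_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep("missing", length(gt))
  out[gt %in% c("0/0")] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt %in% c("1/1")] <- "hom_alt"
  out
}

#' Read trio SNV calls from a VCF
#'
#' Reads a VCF 4.x file carrying `GT` genotypes and the annotation INFO keys
#' `GENE` (symbol), `CSQ` (consequence term), `HGVSC` and optionally `HGVSP`,
#' and joins each variant with the trio genotypes of every proband in the
#' pedigree that carries the alternate allele.
#'
#' @param path VCF file (plain text or gzipped).
#' @param ped a [pedigree] table; every proband and its parents must appear
#'   among the VCF sample columns.
#' @return An `snv_calls` data frame with one row per (proband, variant) for
#'   probands carrying the allele: `sample_id`, `chrom`, `pos`, `variant_id`,
#'   `gene`, `consequence`, `hgvs_c`, `hgvs_p`, `gt_proband`, `gt_father`,
#'   `gt_mother`.
#' @export
read_snv_calls <- function(path, ped) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  pb <- probands(ped)
  fa <- ped$father_id[match(pb, ped$sample_id)]
  mo <- ped$mother_id[match(pb, ped$sample_id)]
  need <- unique(c(pb, fa, mo))
  miss <- setdiff(need, colnames(gt))
  if (length(miss)) {
    stop("pedigree member(s) absent from VCF: ", paste(miss, collapse = ", "))
  }
  info1 <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else unname(x)
  }
  gene <- info1("GENE")
  csq <- info1("CSQ")
  hgvsc <- info1("HGVSC")
  hgvsp <- info1("HGVSP")
  rows <- list()
  for (i in seq_along(pb)) {
    g_p <- map_gt(gt[, pb[i]])
    carrier <- g_p %in% c("het", "hom_alt")
    if (!any(carrier)) next
    rows[[i]] <- data.frame(
      sample_id = pb[i],
      chrom = fix[carrier, "CHROM"],
      pos = as.integer(fix[carrier, "POS"]),
      variant_id = fix[carrier, "ID"],
      gene = gene[carrier],
      consequence = csq[carrier],
      hgvs_c = hgvsc[carrier],
      hgvs_p = hgvsp[carrier],
      gt_proband = g_p[carrier],
      gt_father = map_gt(gt[carrier, fa[i]]),
      gt_mother = map_gt(gt[carrier, mo[i]]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), chrom = character(), pos = integer(),
               variant_id = character(), gene = character(),
               consequence = character(), hgvs_c = character(),
               hgvs_p = character(), gt_proband = character(),
               gt_father = character(), gt_mother = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("snv_calls", "data.frame")
  out
}

#' Write trio SNVs as a minimal annotated VCF
#'
#' Emits a VCF 4.2 file with `GT` genotypes for every sample in `samples` and
#' INFO keys `GENE`, `CSQ`, `HGVSC`, `HGVSP`.
#'
#' @param variants data frame with columns `chrom`, `pos`, `variant_id`,
#'   `ref`, `alt`, `gene`, `consequence`, `hgvs_c`, `hgvs_p`.
#' @param genotypes character matrix (variants x samples) of VCF `GT` strings
#'   such as `"0/1"`.
#' @param samples sample ids (column order of `genotypes`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_snv_vcf <- function(variants, genotypes, samples, path) {
  stopifnot(nrow(genotypes) == nrow(variants),
            ncol(genotypes) == length(samples))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence term\">",
           "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS cDNA change\">",
           "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"HGVS protein change\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  info <- paste0("GENE=", variants$gene, ";CSQ=", variants$consequence,
                 ";HGVSC=", variants$hgvs_c,
                 ifelse(is.na(variants$hgvs_p) | !nzchar(variants$hgvs_p),
                        "", paste0(";HGVSP=", variants$hgvs_p)))
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", info, "GT",
                apply(genotypes, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# --- gene list and region catalog -------------------------------------------

#' Read an ASD gene list
#'
#' TSV with header columns `symbol` and `haploinsufficient` (0/1), in the
#' style of a SFARI-derived gene list.
#'
#' @param path input TSV.
#' @return A data frame with `symbol` (unique) and `haploinsufficient`
#'   (logical).
#' @export
read_gene_list <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  gene_list(d$symbol, d$haploinsufficient)
}

#' Construct a gene list
#' @param symbol gene symbols (unique).
#' @param haploinsufficient logical or 0/1 flag per symbol.
#' @return A `gene_list` data frame.
#' @export
gene_list <- function(symbol, haploinsufficient = rep(FALSE, length(symbol))) {
  if (anyDuplicated(symbol)) stop("duplicate symbols in gene list")
  out <- data.frame(symbol = as.character(symbol),
                    haploinsufficient = as.logical(haploinsufficient),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_list", "data.frame")
  out
}

#' Write a gene list to TSV
#' @param x a [gene_list].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_gene_list <- function(x, path) {
  d <- data.frame(symbol = x$symbol,
                  haploinsufficient = as.integer(x$haploinsufficient))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known syndromic-region catalog
#'
#' TSV with header columns `name`, `chrom`, `start`, `end`, `syndrome`,
#' `key_genes` (semicolon-joined symbols); coordinates 1-based inclusive.
#'
#' @param path input TSV.
#' @return A `region_catalog` data frame.
#' @export
read_region_catalog <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  quote = "")
  region_catalog(d$name, d$chrom, d$start, d$end, d$syndrome, d$key_genes)
}

#' Construct a known-region catalog
#' @param name region name (unique).
#' @param chrom,start,end 1-based inclusive genomic span.
#' @param syndrome associated syndrome label.
#' @param key_genes semicolon-joined key gene symbols.
#' @return A `region_catalog` data frame.
#' @export
region_catalog <- function(name, chrom, start, end, syndrome,
                           key_genes = rep("", length(name))) {
  out <- data.frame(name = as.character(name), chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    syndrome = as.character(syndrome),
                    key_genes = as.character(key_genes),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("catalog region with end <= start")
  if (anyDuplicated(out$name)) stop("duplicate region names")
  class(out) <- c("region_catalog", "data.frame")
  out
}

#' Write a region catalog to TSV
#' @param x a `region_catalog`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_region_catalog <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
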