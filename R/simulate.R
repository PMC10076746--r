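#' Configuration for the synthetic trio cohort
#'
#' Defaults emulate the study design the package targets: 354 trios with a
#' male-skewed proband sex ratio (279:75), peripheral-blood expression with a
#' lognormal baseline per gene, multiplicative lognormal noise (sd 0.2 on the
#' log2 scale), and roughly 40% of genes stably expressed in blood. A small
#' minority of probands carry planted multi-gene CNVs (copy ratio 1.5 or 0.5
#' for heterozygous duplication/deletion) or de novo protein-truncating SNVs
#' that reduce the mutant gene's expression (partial nonsense-mediated
#' decay, ratio 0.6).
#'
#' @param seed integer RNG seed governing every draw.
#' @param n_trios number of trios.
#' @param n_chromosomes,genes_per_chromosome synthetic genome dimensions.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-gene
#'   baseline expression.
#' @param noise_sd multiplicative expression noise, sd on the log2 scale.
#' @param blood_expressed_fraction fraction of genes expressed in blood.
#' @param male_fraction proband male fraction.
#' @param cnvs list of planted CNVs from [plant_cnv()].
#' @param snvs list of planted SNVs from [plant_snv()].
#' @param round_counts round the raw matrix to integer counts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_trios = 354L, n_chromosomes = 2L,
                       genes_per_chromosome = 200L, baseline_meanlog = 6,
                       baseline_sdlog = 1, noise_sd = 0.2,
                       blood_expressed_fraction = 0.4,
                       male_fraction = 279 / 354,
                       cnvs = list(), snvs = list(), round_counts = TRUE) {
  cfg <- list(seed = as.integer(seed), n_trios = as.integer(n_trios),
              n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, noise_sd = noise_sd,
              blood_expressed_fraction = blood_expressed_fraction,
              male_fraction = male_fraction, cnvs = cnvs, snvs = snvs,
              round_counts = isTRUE(round_counts))
  for (v in cfg$cnvs) {
    stopifnot(v$copy_ratio > 0, v$carrier >= 1, v$carrier <= cfg$n_trios)
  }
  for (v in cfg$snvs) {
    stopifnot(v$expression_ratio > 0, v$expression_ratio <= 1,
              v$carrier >= 1, v$carrier <= cfg$n_trios)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Describe a planted CNV
#'
#' The CNV spans a consecutive run of genes on one synthetic chromosome; its
#' genomic span runs from the first gene's start to the last gene's end.
#'
#' @param carrier trio index (1-based) of the carrier proband.
#' @param chrom chromosome index.
#' @param first_gene,n_genes run of covered genes.
#' @param copy_ratio expression ratio of the carrier's in-CNV genes (1.5 for
#'   a heterozygous duplication, 0.5 for a deletion).
#' @param origin `"de_novo"`, `"paternal"` or `"maternal"`.
#' @return A list describing the CNV.
#' @export
plant_cnv <- function(carrier, chrom = 1L, first_gene = 1L, n_genes = 10L,
                      copy_ratio = 1.5,
                      origin = c("de_novo", "paternal", "maternal")) {
  list(carrier = as.integer(carrier), chrom = as.integer(chrom),
       first_gene = as.integer(first_gene), n_genes = as.integer(n_genes),
       copy_ratio = copy_ratio,
       cnv_type = if (copy_ratio >= 1) "duplication" else "deletion",
       origin = match.arg(origin))
}

#' Describe a planted SNV
#'
#' @param carrier trio index of the carrier proband.
#' @param chrom,gene chromosome index and gene index of the mutated gene.
#' @param consequence consequence term (default `"nonsense"`).
#' @param expression_ratio carrier expression of the mutant gene relative to
#'   baseline, in (0, 1] (default 0.6, partial nonsense-mediated decay).
#' @param origin inheritance origin.
#' @return A list describing the SNV.
#' @export
plant_snv <- function(carrier, chrom = 1L, gene = 1L,
                      consequence = "nonsense", expression_ratio = 0.6,
                      origin = c("de_novo", "paternal", "maternal")) {
  stopifnot(consequence %in% CONSEQUENCE_LEVELS)
  list(carrier = as.integer(carrier), chrom = as.integer(chrom),
       gene = as.integer(gene), consequence = consequence,
       expression_ratio = expression_ratio, origin = match.arg(origin))
}

sim_gene_id <- function(chrom, idx) sprintf("G%d_%04d", chrom, idx)

#' Generate the synthetic genome
#'
#' Lays out non-overlapping gene spans per chromosome (widths 2-20 kb,
#' gaps 1-30 kb), deterministically under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return A [gene_models] table.
#' @export
generate_genome <- function(cfg) {
  with_local_seed(cfg$seed * 7L + 1L, {
    rows <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
      n <- cfg$genes_per_chromosome
      if (n == 0L) return(NULL)
      widths <- sample(2000:20000, n, replace = TRUE)
      gaps <- sample(1000:30000, n, replace = TRUE)
      starts <- cumsum(gaps) + c(0L, cumsum(widths)[-n])
      data.frame(gene_id = sim_gene_id(ch, seq_len(n)),
                 chrom = paste0("chr", ch), start = starts,
                 end = starts + widths - 1L, stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    if (is.null(d)) {
      gene_models(character(), character(), integer(), integer())
    } else {
      gene_models(d$gene_id, d$chrom, d$start, d$end)
    }
  })
}

hgvs_for <- function(consequence) {
  switch(consequence,
         nonsense = c("c.1570C>T", "p.Arg524*"),
         frameshift = c("c.546dupA", "p.Leu182fs"),
         splice_donor = c("c.605+1G>A", ""),
         splice_acceptor = c("c.7395-2A>T", ""),
         missense = c("c.100A>G", "p.Lys34Glu"),
         synonymous = c("c.99G>A", "p.Thr33="),
         c("c.1A>T", ""))
}

#' Generate a full synthetic trio cohort
#'
#' Produces a pedigree, trio SNV genotypes, CNV calls for probands and
#' carrier parents, a raw expression matrix over the probands, and a truth
#' table of every planted variant. Blood-silent genes get zero counts in
#' everyone; expressed genes get a lognormal baseline shared across the
#' cohort, multiplied in the carrier by the planted copy ratio (CNVs) or
#' expression ratio (truncating SNVs), then by multiplicative lognormal
#' noise.
#'
#' @param cfg a [sim_config()].
#' @param genes optional [gene_models] (defaults to
#'   [generate_genome()]`(cfg)`).
#' @return A `sim_cohort` list with elements `ped`, `genes`, `expression`
#'   (raw [expr_matrix]), `snvs` (trio `snv_calls`), `snv_variants`,
#'   `snv_genotypes`, `vcf_samples`, `cnvs` ([cnv_calls]), `truth`
#'   (data frame), `blood_expressed` (named logical).
#' @export
generate_cohort <- function(cfg, genes = generate_genome(cfg)) {
  n <- cfg$n_trios
  pb <- sprintf("SIM%04d", seq_len(n))
  fa <- paste0(pb, "_F")
  mo <- paste0(pb, "_M")
  for (v in cfg$cnvs) {
    if (!all(sim_gene_id(v$chrom, v$first_gene + seq_len(v$n_genes) - 1L)
             %in% genes$gene_id)) {
      stop("planted CNV references genes outside the genome")
    }
  }
  for (v in cfg$snvs) {
    if (!sim_gene_id(v$chrom, v$gene) %in% genes$gene_id) {
      stop("planted SNV references a gene outside the genome")
    }
  }

  with_local_seed(cfg$seed * 7L + 2L, {
    n_male <- round(n * cfg$male_fraction)
    sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))
    ped <- pedigree(
      family_id = rep(sprintf("FAM%04d", seq_len(n)), 3L),
      sample_id = c(pb, fa, mo),
      father_id = c(fa, rep("0", 2L * n)),
      mother_id = c(mo, rep("0", 2L * n)),
      sex = c(sex, rep("male", n), rep("female", n)),
      affected = c(rep(TRUE, n), rep(FALSE, 2L * n)))

    g_ids <- genes$gene_id
    expressed <- stats::runif(length(g_ids)) < cfg$blood_expressed_fraction
    names(expressed) <- g_ids
    baseline <- stats::rlnorm(length(g_ids), cfg$baseline_meanlog,
                              cfg$baseline_sdlog)
    names(baseline) <- g_ids

    effect <- matrix(1, nrow = length(g_ids), ncol = n,
                     dimnames = list(g_ids, pb))
    truth <- list()
    cnv_rows <- list()
    for (v in cfg$cnvs) {
      gs <- sim_gene_id(v$chrom, v$first_gene + seq_len(v$n_genes) - 1L)
      span <- genes[match(gs, genes$gene_id), ]
      effect[gs, v$carrier] <- effect[gs, v$carrier] * v$copy_ratio
      cnv_rows[[length(cnv_rows) + 1L]] <- data.frame(
        sample_id = pb[v$carrier], chrom = paste0("chr", v$chrom),
        start = min(span$start), end = max(span$end),
        cnv_type = v$cnv_type, stringsAsFactors = FALSE)
      if (v$origin != "de_novo") {
        par_id <- if (v$origin == "paternal") fa[v$carrier] else
          mo[v$carrier]
        cnv_rows[[length(cnv_rows) + 1L]] <- data.frame(
          sample_id = par_id, chrom = paste0("chr", v$chrom),
          start = min(span$start), end = max(span$end),
          cnv_type = v$cnv_type, stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        carrier = pb[v$carrier], variant_type = "cnv",
        key = paste0("chr", v$chrom, ":", min(span$start), "-",
                     max(span$end), ":", v$cnv_type),
        gene = NA_character_, origin = v$origin,
        effect_ratio = v$copy_ratio,
        direction = if (v$copy_ratio >= 1) "up" else "down",
        stringsAsFactors = FALSE)
    }

    snv_variants <- list()
    gt <- NULL
    samples <- c(pb, fa, mo)
    for (v in cfg$snvs) {
      gid <- sim_gene_id(v$chrom, v$gene)
      effect[gid, v$carrier] <- effect[gid, v$carrier] * v$expression_ratio
      hg <- hgvs_for(v$consequence)
      gm <- genes[genes$gene_id == gid, ]
      row_gt <- rep("0/0", length(samples))
      names(row_gt) <- samples
      row_gt[pb[v$carrier]] <- "0/1"
      if (v$origin == "paternal") row_gt[fa[v$carrier]] <- "0/1"
      if (v$origin == "maternal") row_gt[mo[v$carrier]] <- "0/1"
      snv_variants[[length(snv_variants) + 1L]] <- data.frame(
        chrom = gm$chrom, pos = gm$start + 100L,
        variant_id = paste0("snv_", pb[v$carrier], "_", gid),
        ref = "A", alt = "T", gene = gid, consequence = v$consequence,
        hgvs_c = hg[1L], hgvs_p = hg[2L], stringsAsFactors = FALSE)
      gt <- rbind(gt, row_gt)
      truth[[length(truth) + 1L]] <- data.frame(
        carrier = pb[v$carrier], variant_type = "snv",
        key = paste0(gid, ":", hg[1L]), gene = gid, origin = v$origin,
        effect_ratio = v$expression_ratio, direction = "down",
        stringsAsFactors = FALSE)
    }
    snv_variants <- if (length(snv_variants)) {
      do.call(rbind, snv_variants)
    } else {
      data.frame(chrom = character(), pos = integer(),
                 variant_id = character(), ref = character(),
                 alt = character(), gene = character(),
                 consequence = character(), hgvs_c = character(),
                 hgvs_p = character(), stringsAsFactors = FALSE)
    }

    noise <- matrix(2^stats::rnorm(length(g_ids) * n, 0, cfg$noise_sd),
                    nrow = length(g_ids))
    vals <- baseline * effect * noise
    vals[!expressed, ] <- 0
    if (cfg$round_counts) vals <- round(vals)
    dimnames(vals) <- list(g_ids, pb)
    expression <- expr_matrix(vals, normalized = FALSE)

    snvs <- if (nrow(snv_variants)) {
      idx <- seq_len(nrow(snv_variants))
      carriers <- vapply(idx, function(i) {
        p <- intersect(names(which(gt[i, ] == "0/1")), pb)
        p[1L]
      }, "")
      out <- data.frame(
        sample_id = carriers, chrom = snv_variants$chrom,
        pos = snv_variants$pos, variant_id = snv_variants$variant_id,
        gene = snv_variants$gene, consequence = snv_variants$consequence,
        hgvs_c = snv_variants$hgvs_c, hgvs_p = snv_variants$hgvs_p,
        gt_proband = map_gt(gt[cbind(idx, match(carriers, samples))]),
        gt_father = map_gt(gt[cbind(idx, match(paste0(carriers, "_F"),
                                               samples))]),
        gt_mother = map_gt(gt[cbind(idx, match(paste0(carriers, "_M"),
                                               samples))]),
        stringsAsFactors = FALSE)
      class(out) <- c("snv_calls", "data.frame")
      out
    } else {
      structure(data.frame(), class = c("snv_calls", "data.frame"))
    }

    cnvs <- if (length(cnv_rows)) {
      d <- do.call(rbind, cnv_rows)
      cnv_calls(d$sample_id, d$chrom, d$start, d$end, d$cnv_type)
    } else {
      cnv_calls(character(), character(), integer(), integer(), character())
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(carrier = character(), variant_type = character(),
                 key = character(), gene = character(), origin = character(),
                 effect_ratio = numeric(), direction = character(),
                 stringsAsFactors = FALSE)

    structure(list(ped = ped, genes = genes, expression = expression,
                   snvs = snvs, snv_variants = snv_variants,
                   snv_genotypes = gt, vcf_samples = samples, cnvs = cnvs,
                   truth = truth, blood_expressed = expressed,
                   baseline = baseline),
              class = "sim_cohort")
  })
}

#' Gene list implied by a simulated cohort's planted SNVs
#'
#' Every gene carrying a planted SNV, flagged haploinsufficient, plus any
#' extra symbols supplied.
#'
#' @param cohort a `sim_cohort`.
#' @param extra additional symbols to include.
#' @return A [gene_list].
#' @export
truth_gene_list <- function(cohort, extra = character()) {
  syms <- unique(c(cohort$truth$gene[cohort$truth$variant_type == "snv"],
                   extra))
  syms <- syms[!is.na(syms)]
  gene_list(syms, rep(TRUE, length(syms)))
}

#' Region catalog implied by a simulated cohort's planted CNVs
#'
#' @param cohort a `sim_cohort`.
#' @return A `region_catalog` with one entry per planted CNV span.
#' @export
truth_catalog <- function(cohort) {
  tc <- cohort$truth[cohort$truth$variant_type == "cnv", , drop = FALSE]
  if (nrow(tc) == 0L) {
    return(region_catalog(character(), character(), integer(), integer(),
                          character()))
  }
  parts <- regmatches(tc$key,
                      regexec("^(chr[0-9]+):([0-9]+)-([0-9]+):", tc$key))
  d <- unique(data.frame(
    chrom = vapply(parts, `[[`, "", 2L),
    start = as.integer(vapply(parts, `[[`, "", 3L)),
    end = as.integer(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE))
  region_catalog(name = paste0("region_", seq_len(nrow(d))), chrom = d$chrom,
                 start = d$start, end = d$end,
                 syndrome = paste0("synthetic syndrome ", seq_len(nrow(d))))
}

#' Write every file of a simulated cohort
#'
#' Emits the on-disk form of each collection: `pedigree.ped`, `snvs.vcf`,
#' `cnvs.tsv`, `expression.tsv`, `genes.tsv`, `truth.tsv`.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(cohort$ped, file.path(dir, "pedigree.ped"))
  write_snv_vcf(cohort$snv_variants, cohort$snv_genotypes,
                cohort$vcf_samples, file.path(dir, "snvs.vcf"))
  write_cnv_calls(cohort$cnvs, file.path(dir, "cnvs.tsv"))
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_gene_models(cohort$genes, file.path(dir, "genes.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate a synthetic qPCR plate from a true copy ratio
#'
#' The test sample's target Cq sits `log_E(ratio)` cycles before the
#' calibrator's, plus Gaussian measurement noise on the test sample's wells;
#' the calibrator wells anchor the plate and are noise-free by construction,
#' so a noise-free plate recovers the ratio exactly.
#'
#' @param ratio true relative copy number of the test sample (calibrator
#'   at 1).
#' @param efficiency amplification factor per cycle (default 2).
#' @param noise_sd Gaussian Cq noise sd in cycles (default 0).
#' @param seed RNG seed.
#' @param target_gene,sample_id,calibrator_id labels.
#' @param n_replicates technical replicates per well group (default 3).
#' @return A [qpcr_plate].
#' @export
generate_qpcr_plate <- function(ratio, efficiency = 2, noise_sd = 0,
                                seed = 1L, target_gene = "CNV1",
                                sample_id = "S1", calibrator_id = "CTRL",
                                n_replicates = 3L) {
  stopifnot(ratio > 0)
  with_local_seed(seed, {
    base_t <- 25
    base_r <- 20
    cq <- function(center) center + stats::rnorm(n_replicates, 0, noise_sd)
    rows <- rbind(
      data.frame(sample_id = calibrator_id, target_gene = target_gene,
                 role = "target", is_calibrator = TRUE,
                 cq = rep(base_t, n_replicates), stringsAsFactors = FALSE),
      data.frame(sample_id = calibrator_id, target_gene = "GAPDH",
                 role = "reference", is_calibrator = TRUE,
                 cq = rep(base_r, n_replicates), stringsAsFactors = FALSE),
      data.frame(sample_id = sample_id, target_gene = target_gene,
                 role = "target", is_calibrator = FALSE,
                 cq = cq(base_t - log(ratio) / log(efficiency)),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = sample_id, target_gene = "GAPDH",
                 role = "reference", is_calibrator = FALSE,
                 cq = cq(base_r), stringsAsFactors = FALSE))
    rows$replicate <- stats::ave(seq_len(nrow(rows)),
                                 paste(rows$sample_id, rows$target_gene),
                                 FUN = seq_along)
    qpcr_plate(rows$sample_id, rows$target_gene, rows$role,
               rows$is_calibrator, rows$replicate, rows$cq,
               efficiency = rep(efficiency, nrow(rows)))
  })
}

random_seq <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
}

#' Generate paired reads with planted QC violations
#'
#' Plants exact numbers of N-rich pairs (one mate with `max_n + 1` Ns),
#' low-quality pairs (one mate with just over the tolerated fraction of
#' bases below the Phred threshold) and adapter-flagged pairs; the remainder
#' are clean, with boundary reads (exactly `max_n` Ns, exactly the tolerated
#' low-quality fraction) available via `boundary`.
#'
#' @param n_pairs total number of pairs.
#' @param n_n_rich,n_lowq,n_adapter planted violation counts.
#' @param read_length read length (default 150).
#' @param max_n,lowq_threshold,lowq_fraction the QC thresholds the plants
#'   are constructed against.
#' @param boundary number of clean pairs built exactly at both boundaries.
#' @param seed RNG seed.
#' @return A list: `pairs` (a [read_pairs]) and `truth` (character vector:
#'   `"clean"`, `"n_rich"`, `"lowq"`, `"adapter"`).
#' @export
generate_fastq_pairs <- function(n_pairs, n_n_rich = 0L, n_lowq = 0L,
                                 n_adapter = 0L, read_length = 150L,
                                 max_n = 3L, lowq_threshold = 5L,
                                 lowq_fraction = 0.20, boundary = 0L,
                                 seed = 1L) {
  stopifnot(n_n_rich + n_lowq + n_adapter + boundary <= n_pairs)
  with_local_seed(seed, {
    good_q <- strrep(rawToChar(as.raw(33L + 35L)), read_length)  # Phred 35
    low_char <- rawToChar(as.raw(33L + lowq_threshold - 1L))
    seqs1 <- random_seq(n_pairs, read_length)
    seqs2 <- random_seq(n_pairs, read_length)
    qual1 <- rep(good_q, n_pairs)
    qual2 <- rep(good_q, n_pairs)
    adapter <- rep(FALSE, n_pairs)
    truth <- rep("clean", n_pairs)
    slot <- 0L
    take <- function(k) {
      idx <- slot + seq_len(k)
      slot <<- slot + k
      idx
    }
    for (i in take(n_n_rich)) {
      truth[i] <- "n_rich"
      seqs1[i] <- paste0(strrep("N", max_n + 1L),
                         substr(seqs1[i], max_n + 2L, read_length))
    }
    n_low <- floor(read_length * lowq_fraction) + 1L
    for (i in take(n_lowq)) {
      truth[i] <- "lowq"
      qual2[i] <- paste0(strrep(low_char, n_low),
                         substr(qual2[i], n_low + 1L, read_length))
    }
    for (i in take(n_adapter)) {
      truth[i] <- "adapter"
      adapter[i] <- TRUE
    }
    n_low_edge <- floor(read_length * lowq_fraction)
    for (i in take(boundary)) {
      seqs1[i] <- paste0(strrep("N", max_n),
                         substr(seqs1[i], max_n + 1L, read_length))
      qual2[i] <- paste0(strrep(low_char, n_low_edge),
                         substr(qual2[i], n_low_edge + 1L, read_length))
    }
    pairs <- read_pairs(id = sprintf("read%05d", seq_len(n_pairs)),
                        seq1 = seqs1, qual1 = qual1,
                        seq2 = seqs2, qual2 = qual2, adapter = adapter)
    list(pairs = pairs, truth = truth)
  })
}
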