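#' Classify inheritance origin from trio genotypes
#'
#' Based on carrier status (het or hom_alt) of the three trio members: a
#' proband allele seen in neither parent is de novo; in one parent, paternal
#' or maternal; in both, inherited from both. A proband that does not carry
#' the allele, or a trio with a missing relevant genotype, is ambiguous.
#'
#' @param proband,father,mother genotype strings, each one of `"hom_ref"`,
#'   `"het"`, `"hom_alt"`, `"missing"`; vectorized.
#' @return Character vector: `"de_novo"`, `"paternal"`, `"maternal"`,
#'   `"inherited_both"` or `"ambiguous"`.
#' @export
classify_origin <- function(proband, father, mother) {
  stopifnot(all(proband %in% GT_LEVELS), all(father %in% GT_LEVELS),
            all(mother %in% GT_LEVELS))
  carries <- function(g) g %in% c("het", "hom_alt")
  out <- rep("ambiguous", length(proband))
  ok <- carries(proband) & father != "missing" & mother != "missing"
  fa <- carries(father)
  mo <- carries(mother)
  out[ok & !fa & !mo] <- "de_novo"
  out[ok & fa & !mo] <- "paternal"
  out[ok & !fa & mo] <- "maternal"
  out[ok & fa & mo] <- "inherited_both"
  out
}

splice_offset <- function(hgvs_c) {
  h <- gsub("[[:space:]]", "", hgvs_c)
  m <- regmatches(h, regexec("^c\\.[0-9_*]+([+-][0-9]+)", h))
  vapply(m, function(x) {
    if (length(x) < 2L) NA_integer_ else as.integer(x[2L])
  }, NA_integer_)
}

#' Is a variant protein-truncating?
#'
#' Protein-truncating variants (PTVs) are nonsense and frameshift changes,
#' plus splice-donor/acceptor variants at the canonical +/-1 or +/-2 intronic
#' positions (offset parsed from the HGVS cDNA string, e.g. `c.605+1G>A` or
#' `c.7395-2A>T`). Deeper splice-region variants and all missense/synonymous
#' changes are not PTVs.
#'
#' @param consequence consequence term(s), one of `"nonsense"`,
#'   `"frameshift"`, `"splice_donor"`, `"splice_acceptor"`, `"missense"`,
#'   `"synonymous"`, `"other"`.
#' @param hgvs_c HGVS cDNA strings (needed only for splice consequences).
#' @param max_splice_offset canonical-site window (default 2).
#' @return Logical vector.
#' @export
classify_ptv <- function(consequence, hgvs_c = rep(NA_character_,
                                                   length(consequence)),
                         max_splice_offset = 2L) {
  stopifnot(all(consequence %in% CONSEQUENCE_LEVELS))
  out <- consequence %in% c("nonsense", "frameshift")
  sp <- consequence %in% c("splice_donor", "splice_acceptor")
  if (any(sp)) {
    off <- splice_offset(hgvs_c[sp])
    if (anyNA(off)) {
      stop("cannot parse splice offset from HGVS: ",
           paste(hgvs_c[sp][is.na(off)], collapse = ", "))
    }
    out[sp] <- abs(off) <= max_splice_offset
  }
  out
}

#' Does a CNV pass the calling-resolution filter?
#'
#' @param cnvs a [cnv_calls] table.
#' @param min_size minimum size in bp (default 100 kb, the resolution of
#'   low-depth WGS CNV calling); the boundary is inclusive.
#' @return Logical vector along rows of `cnvs`.
#' @export
filter_cnv_resolution <- function(cnvs, min_size = 100000L) {
  cnvs$size >= min_size
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
  cbind(q = ov / (e1 - s1 + 1), r = ov / (e2 - s2 + 1))
}

#' Match a CNV against a catalog of known syndromic regions
#'
#' A catalog region matches when the overlap covers at least
#' `min_reciprocal_overlap` of the CNV and of the region. Among qualifying
#' regions the one with maximal reciprocal overlap (the smaller of the two
#' coverage fractions) wins; ties break to the smaller region, then to the
#' lexicographically first name.
#'
#' @param cnv one-row [cnv_calls] table.
#' @param catalog a `region_catalog`.
#' @param min_reciprocal_overlap threshold in (0, 1] (default 0.5).
#' @return The matching one-row catalog entry, or `NULL`.
#' @export
match_known_region <- function(cnv, catalog, min_reciprocal_overlap = 0.5) {
  stopifnot(nrow(cnv) == 1L)
  cand <- catalog[catalog$chrom == cnv$chrom, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  ro <- reciprocal_overlap(cnv$start, cnv$end, cand$start, cand$end)
  keep <- ro[, "q"] >= min_reciprocal_overlap &
    ro[, "r"] >= min_reciprocal_overlap
  if (!any(keep)) return(NULL)
  cand <- cand[keep, , drop = FALSE]
  score <- pmin(ro[keep, "q"], ro[keep, "r"])
  size <- cand$end - cand$start + 1L
  ord <- order(-score, size, cand$name)
  cand[ord[1L], , drop = FALSE]
}

#' Inheritance origin of a proband CNV from parental call sets
#'
#' A parent carries the CNV when any of that parent's calls of the same type
#' reciprocally overlaps the proband call at `min_reciprocal_overlap` or
#' more. Origin then follows the trio rule: neither parent carries it
#' (de novo), one parent (paternal/maternal), both (inherited_both).
#'
#' @param proband_cnv one-row [cnv_calls] table.
#' @param father_cnvs,mother_cnvs [cnv_calls] tables of parental calls (may
#'   be empty).
#' @param min_reciprocal_overlap threshold (default 0.5).
#' @return One of `"de_novo"`, `"paternal"`, `"maternal"`,
#'   `"inherited_both"`.
#' @export
cnv_origin <- function(proband_cnv, father_cnvs, mother_cnvs,
                       min_reciprocal_overlap = 0.5) {
  stopifnot(nrow(proband_cnv) == 1L)
  carries <- function(calls) {
    if (is.null(calls) || nrow(calls) == 0L) return(FALSE)
    same <- calls[calls$chrom == proband_cnv$chrom &
                    calls$cnv_type == proband_cnv$cnv_type, , drop = FALSE]
    if (nrow(same) == 0L) return(FALSE)
    ro <- reciprocal_overlap(proband_cnv$start, proband_cnv$end,
                             same$start, same$end)
    any(ro[, "q"] >= min_reciprocal_overlap &
          ro[, "r"] >= min_reciprocal_overlap)
  }
  fa <- carries(father_cnvs)
  mo <- carries(mother_cnvs)
  if (fa && mo) "inherited_both"
  else if (fa) "paternal"
  else if (mo) "maternal"
  else "de_novo"
}

#' Diagnostic triage of trio SNV and CNV calls
#'
#' Applies the cohort's diagnostic filter. A proband is SNV-positive when it
#' carries at least one de novo protein-truncating variant in a listed ASD
#' gene. It is CNV-positive when it carries at least one CNV at or above the
#' calling resolution that either matches the known-region catalog by
#' reciprocal overlap (any inheritance origin) or deletes a
#' haploinsufficiency-flagged listed gene. All qualifying findings are
#' reported, one row each; de-duplicated per (proband, variant) and returned
#' in a canonical sort order so the result is invariant to input order.
#'
#' @param snvs an `snv_calls` table (see [read_snv_calls()]); may be empty.
#' @param cnvs a [cnv_calls] table holding calls for probands and parents;
#'   may be empty.
#' @param ped a [pedigree] covering every sample referenced.
#' @param genes_of_interest a [gene_list].
#' @param catalog a `region_catalog` of known syndromic regions.
#' @param models optional [gene_models] used to resolve gene spans for the
#'   haploinsufficient-deletion rule.
#' @param min_cnv_size CNV resolution in bp (default 100000).
#' @param min_reciprocal_overlap reciprocal-overlap threshold (default 0.5).
#' @param max_splice_offset canonical splice window (default 2).
#' @return A `findings` data frame with columns `sample_id`, `variant_type`
#'   (`"snv"`/`"cnv"`), `chrom`, `start`, `end`, `gene`, `consequence`,
#'   `hgvs_c`, `cnv_type`, `size`, `origin`, `matched_region`, `syndrome`.
#' @export
triage <- function(snvs, cnvs, ped, genes_of_interest, catalog,
                   models = NULL, min_cnv_size = 100000L,
                   min_reciprocal_overlap = 0.5, max_splice_offset = 2L) {
  pb <- probands(ped)
  finding_row <- function(sample_id, variant_type, chrom = NA, start = NA,
                          end = NA, gene = NA, consequence = NA, hgvs_c = NA,
                          cnv_type = NA, size = NA, origin = NA,
                          matched_region = NA, syndrome = NA) {
    data.frame(sample_id = sample_id, variant_type = variant_type,
               chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end), gene = as.character(gene),
               consequence = as.character(consequence),
               hgvs_c = as.character(hgvs_c),
               cnv_type = as.character(cnv_type), size = as.integer(size),
               origin = as.character(origin),
               matched_region = as.character(matched_region),
               syndrome = as.character(syndrome), stringsAsFactors = FALSE)
  }
  rows <- list()

  if (!is.null(snvs) && nrow(snvs) > 0L) {
    bad <- setdiff(unique(snvs$sample_id), pb)
    if (length(bad)) {
      stop("SNV sample(s) not probands of the pedigree: ",
           paste(bad, collapse = ", "))
    }
    origin <- classify_origin(snvs$gt_proband, snvs$gt_father,
                              snvs$gt_mother)
    ptv <- classify_ptv(snvs$consequence, snvs$hgvs_c, max_splice_offset)
    hit <- origin == "de_novo" & ptv &
      snvs$gene %in% genes_of_interest$symbol
    for (i in which(hit)) {
      rows[[length(rows) + 1L]] <- finding_row(
        snvs$sample_id[i], "snv", chrom = snvs$chrom[i],
        start = snvs$pos[i], end = snvs$pos[i], gene = snvs$gene[i],
        consequence = snvs$consequence[i], hgvs_c = snvs$hgvs_c[i],
        origin = origin[i])
    }
  }

  if (!is.null(cnvs) && nrow(cnvs) > 0L) {
    bad <- setdiff(unique(cnvs$sample_id), ped$sample_id)
    if (length(bad)) {
      stop("CNV sample(s) missing from pedigree: ",
           paste(bad, collapse = ", "))
    }
    hi_genes <- genes_of_interest$symbol[genes_of_interest$haploinsufficient]
    hi_models <- if (!is.null(models)) {
      models[models$gene_id %in% hi_genes, , drop = FALSE]
    }
    for (p in intersect(unique(cnvs$sample_id), pb)) {
      fa <- ped$father_id[ped$sample_id == p]
      mo <- ped$mother_id[ped$sample_id == p]
      mine <- cnvs[cnvs$sample_id == p, , drop = FALSE]
      mine <- mine[filter_cnv_resolution(mine, min_cnv_size), , drop = FALSE]
      for (i in seq_len(nrow(mine))) {
        call <- mine[i, , drop = FALSE]
        region <- match_known_region(call, catalog, min_reciprocal_overlap)
        hi_del <- FALSE
        hi_gene <- NA_character_
        if (call$cnv_type == "deletion" && !is.null(hi_models) &&
            nrow(hi_models) > 0L) {
          hits <- GenomicRanges::findOverlaps(
            gene_ranges(hi_models), cnv_ranges(call))
          if (length(hits)) {
            hi_del <- TRUE
            hi_gene <- hi_models$gene_id[S4Vectors::queryHits(hits)[1L]]
          }
        }
        if (is.null(region) && !hi_del) next
        org <- if (!is.na(call$origin) && call$origin %in% ORIGIN_LEVELS) {
          call$origin
        } else {
          cnv_origin(call,
                     cnvs[cnvs$sample_id == fa, , drop = FALSE],
                     cnvs[cnvs$sample_id == mo, , drop = FALSE],
                     min_reciprocal_overlap)
        }
        rows[[length(rows) + 1L]] <- finding_row(
          p, "cnv", chrom = call$chrom, start = call$start, end = call$end,
          gene = hi_gene, cnv_type = call$cnv_type, size = call$size,
          origin = org,
          matched_region = if (is.null(region)) NA else region$name,
          syndrome = if (is.null(region)) NA else region$syndrome)
      }
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    finding_row("", "")[0, ]
  key <- paste(out$sample_id, out$variant_type, out$chrom, out$start,
               out$end, out$gene)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$sample_id, out$variant_type, out$chrom, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("findings", "data.frame")
  out
}

#' Write triage findings to TSV
#' @param x a `findings` table from [triage()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_findings <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
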