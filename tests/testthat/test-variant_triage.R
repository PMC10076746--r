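test_that("classify_origin agrees with brute-force enumeration of all triples", {
  states <- c("hom_ref", "het", "hom_alt", "missing")
  oracle <- function(p, f, m) {
    # independent restatement of the trio rule
    carries <- function(g) g == "het" || g == "hom_alt"
    if (!carries(p) || f == "missing" || m == "missing") return("ambiguous")
    if (carries(f) && carries(m)) return("inherited_both")
    if (carries(f)) return("paternal")
    if (carries(m)) return("maternal")
    "de_novo"
  }
  grid <- expand.grid(p = states, f = states, m = states,
                      stringsAsFactors = FALSE)
  expected <- mapply(oracle, grid$p, grid$f, grid$m)
  expect_equal(classify_origin(grid$p, grid$f, grid$m), unname(expected))
})

test_that("classify_origin reproduces the canonical trio cases", {
  expect_equal(classify_origin("het", "hom_ref", "hom_ref"), "de_novo")
  expect_equal(classify_origin("het", "het", "hom_ref"), "paternal")
  expect_equal(classify_origin("het", "missing", "hom_ref"), "ambiguous")
})

test_that("protein-truncating classification covers nonsense, frameshift and canonical splice", {
  expect_true(classify_ptv("nonsense", "c.4242T>G"))
  expect_true(classify_ptv("frameshift", "c.8595delT"))
  expect_true(classify_ptv("splice_acceptor", "c.7395-2A>T"))  # offset -2
  expect_true(classify_ptv("splice_donor", "c.605 + 1G>A"))    # offset +1
  expect_false(classify_ptv("splice_donor", "c.605+3G>A"))     # beyond window
  expect_false(classify_ptv("missense", "c.100A>G"))
  expect_false(classify_ptv("synonymous", "c.99G>A"))
  expect_error(classify_ptv("splice_donor", "c.notanoffset"), "parse")
})

test_that("CNV resolution filter is inclusive at the boundary", {
  cn <- cnv_calls(c("a", "b", "c"), rep("chr1", 3),
                  c(1L, 1L, 1L), c(650588L, 99999L, 100000L),
                  rep("deletion", 3))
  expect_equal(filter_cnv_resolution(cn), c(TRUE, FALSE, TRUE))
})

test_that("known-region matching follows reciprocal overlap against an interval oracle", {
  catalog <- region_catalog(
    name = c("15q11q13_BP2-BP3", "small_region"),
    chrom = c("chr15", "chr15"),
    start = c(23597027L, 1000000L), end = c(28729564L, 1100000L),
    syndrome = c("PWS/AS region", "other"))
  # the 15q duplication span matches its recurrent region both ways
  cnv <- cnv_calls("S1", "chr15", 23596697L, 28012138L, "duplication")
  hit <- match_known_region(cnv, catalog)
  expect_equal(hit$name, "15q11q13_BP2-BP3")
  # exhaustive intersection arithmetic as the oracle
  ov <- min(28012138, 28729564) - max(23596697, 23597027) + 1
  expect_gte(ov / (28012138 - 23596697 + 1), 0.5)
  expect_gte(ov / (28729564 - 23597027 + 1), 0.5)

  # disjoint chromosome -> no match
  cnv2 <- cnv_calls("S1", "chr1", 23596697L, 28012138L, "duplication")
  expect_null(match_known_region(cnv2, catalog))

  # 40% reciprocal overlap both ways -> below the 0.5 threshold
  catalog3 <- region_catalog("r", "chr1", 1L, 1000L, "syn")
  cnv3 <- cnv_calls("S1", "chr1", 601L, 1600L, "duplication")
  ov3 <- 1000 - 601 + 1
  expect_equal(ov3 / 1000, 0.4)
  expect_null(match_known_region(cnv3, catalog3))
})

test_that("region match ties break to the smaller region then name", {
  cnv <- cnv_calls("S1", "chr1", 1L, 1000L, "duplication")
  catalog <- region_catalog(c("b_wide", "a_exact", "c_exact"),
                            rep("chr1", 3), c(1L, 1L, 1L),
                            c(1400L, 1000L, 1000L), rep("syn", 3))
  expect_equal(match_known_region(cnv, catalog)$name, "a_exact")
})

test_that("CNV origin follows parental reciprocal-overlap carriage", {
  pr <- cnv_calls("P", "chr1", 1000L, 2000L, "duplication")
  none <- cnv_calls(character(), character(), integer(), integer(),
                    character())
  near <- cnv_calls("F", "chr1", 950L, 2100L, "duplication")
  wrong_type <- cnv_calls("F", "chr1", 950L, 2100L, "deletion")
  far <- cnv_calls("M", "chr1", 1900L, 4000L, "duplication")
  expect_equal(cnv_origin(pr, none, none), "de_novo")
  expect_equal(cnv_origin(pr, near, none), "paternal")
  expect_equal(cnv_origin(pr, none, near), "maternal")
  expect_equal(cnv_origin(pr, near, near), "inherited_both")
  expect_equal(cnv_origin(pr, wrong_type, none), "de_novo")
  expect_equal(cnv_origin(pr, none, far), "de_novo")  # overlap below 0.5
})

make_triage_inputs <- function() {
  ped <- rbind(trio_ped("P1"), trio_ped("P2"))
  class(ped) <- c("pedigree", "data.frame")
  snvs <- data.frame(
    sample_id = c("P1", "P2", "P2"),
    chrom = "chr1", pos = c(100L, 200L, 300L),
    variant_id = c("v1", "v2", "v3"),
    gene = c("GENE1", "GENE1", "GENE2"),
    consequence = c("nonsense", "missense", "frameshift"),
    hgvs_c = c("c.1C>T", "c.2A>G", "c.3del"), hgvs_p = "",
    gt_proband = "het",
    gt_father = c("hom_ref", "hom_ref", "het"),
    gt_mother = "hom_ref", stringsAsFactors = FALSE)
  class(snvs) <- c("snv_calls", "data.frame")
  cnvs <- cnv_calls(
    sample_id = c("P2", "P2_M", "P1"),
    chrom = c("chr2", "chr2", "chr3"),
    start = c(1e6L, 1e6L, 1L), end = c(2e6L, 2e6L, 50000L),
    cnv_type = "duplication")
  gl <- gene_list(c("GENE1", "GENE2", "HIGENE"), c(FALSE, FALSE, TRUE))
  catalog <- region_catalog("dup_region", "chr2", 1e6L, 2e6L, "syndrome")
  list(ped = ped, snvs = snvs, cnvs = cnvs, gl = gl, catalog = catalog)
}

test_that("triage keeps de novo PTVs in listed genes and catalog CNVs of any origin", {
  x <- make_triage_inputs()
  f <- triage(x$snvs, x$cnvs, x$ped, x$gl, x$catalog)
  # P1 nonsense de novo -> kept; P2 missense -> dropped;
  # P2 frameshift paternal -> dropped (inherited SNVs never qualify)
  expect_equal(f$sample_id[f$variant_type == "snv"], "P1")
  # P2 inherited maternal duplication matches the catalog -> kept;
  # P1 50 kb CNV fails resolution
  cnv_f <- f[f$variant_type == "cnv", ]
  expect_equal(cnv_f$sample_id, "P2")
  expect_equal(cnv_f$origin, "maternal")
  expect_equal(cnv_f$matched_region, "dup_region")
})

test_that("a deletion of a haploinsufficient listed gene qualifies without catalog match", {
  x <- make_triage_inputs()
  models <- gene_models("HIGENE", "chr4", 1000000L, 1050000L)
  cnvs <- cnv_calls("P1", "chr4", 900000L, 1100000L, "deletion")
  f <- triage(x$snvs[0, ], cnvs, x$ped, x$gl, x$catalog, models = models)
  expect_equal(nrow(f), 1L)
  expect_equal(f$gene, "HIGENE")
  expect_equal(f$origin, "de_novo")
  # the same span as a duplication does not qualify
  f2 <- triage(x$snvs[0, ],
               cnv_calls("P1", "chr4", 900000L, 1100000L, "duplication"),
               x$ped, x$gl, x$catalog, models = models)
  expect_equal(nrow(f2), 0L)
})

test_that("triage output is order-invariant and duplicate-free", {
  x <- make_triage_inputs()
  f1 <- triage(x$snvs, x$cnvs, x$ped, x$gl, x$catalog)
  shuf <- x$snvs[c(3, 1, 2), ]
  class(shuf) <- c("snv_calls", "data.frame")
  dup <- rbind(shuf, shuf[2, ])
  class(dup) <- c("snv_calls", "data.frame")
  f2 <- triage(dup, x$cnvs[c(3, 1, 2), ], x$ped, x$gl, x$catalog)
  expect_equal(f1, f2)
})

test_that("a variant for a sample outside the pedigree is an error", {
  x <- make_triage_inputs()
  orphan <- x$snvs
  orphan$sample_id[1] <- "GHOST"
  class(orphan) <- c("snv_calls", "data.frame")
  expect_error(triage(orphan, x$cnvs, x$ped, x$gl, x$catalog), "GHOST")
})

test_that("the bundled cohort reproduces the published triage tallies", {
  d <- demo_cohort()
  f <- triage(d$snvs, d$cnvs, d$ped, d$genes_of_interest, d$catalog)
  expect_equal(length(unique(f$sample_id[f$variant_type == "snv"])), 10L)
  expect_equal(length(unique(f$sample_id[f$variant_type == "cnv"])), 9L)
  expect_true(all(f$origin[f$variant_type == "snv"] == "de_novo"))
  cnv_f <- f[f$variant_type == "cnv", ]
  expect_equal(sum(cnv_f$origin == "de_novo"), 5L)
  expect_equal(sum(cnv_f$origin %in% c("paternal", "maternal")), 4L)
  expect_equal(sum(cnv_f$cnv_type == "duplication"), 6L)
  expect_equal(sum(cnv_f$cnv_type == "deletion"), 3L)
  expect_equal(sum(f$gene == "SCN2A", na.rm = TRUE), 3L)
})
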