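# minimal annotated-variant row for direct tier-rule checks
tier_row <- function(impact = "MODERATE", em = NULL, hotspot = FALSE,
                     onc = FALSE, tsg = FALSE, census = FALSE, score = 0,
                     gene = "G1", pos = 100L) {
  v <- data.frame(chrom = "1", pos = pos, ref = "A", alt = "T",
                  variant_class = "SNV", gene_symbol = gene,
                  transcript_id = "TX", consequence = "x", hgvsp = "",
                  hgvsc = "", impact = impact, stringsAsFactors = FALSE)
  v$evidence_matches <- list(em)
  v$frequencies <- list(NULL)
  v$hotspot_overlap <- hotspot
  v$hotspot_source <- if (hotspot) "hotspot" else ""
  v$patho_n_algorithms <- 0L
  v$patho_n_damaging <- 0L
  v$patho_label <- "unknown"
  v$gene_known <- TRUE
  v$is_oncogene <- onc
  v$is_tsg <- tsg
  v$in_census <- census
  v$literature_score <- score
  v$gene_drugs <- ""
  v
}
ev_match <- function(level, granularity, id = "EV1") {
  data.frame(evidence_id = id, granularity = granularity,
             evidence_level = level, evidence_type = "predictive",
             clinical_significance = "sensitivity", tumor_type = "any",
             tumor_type_concordant = FALSE, drug = "DRUG_A",
             citation = "PMID:1", stringsAsFactors = FALSE)
}

test_that("the five tier rules fire in order, first match wins", {
  expect_equal(assign_tiers(tier_row(em = ev_match("A", "exact_allele")))$tier, 1L)
  expect_equal(assign_tiers(tier_row(em = ev_match("B", "codon")))$tier, 1L)
  # gene-granularity A/B evidence does not reach Tier 1 or 2
  expect_equal(assign_tiers(tier_row(em = ev_match("B", "gene"), onc = TRUE))$tier, 3L)
  expect_equal(assign_tiers(tier_row(em = ev_match("C", "gene")))$tier, 2L)
  expect_equal(assign_tiers(tier_row(hotspot = TRUE))$tier, 2L)
  expect_equal(assign_tiers(tier_row(onc = TRUE))$tier, 3L)
  expect_equal(assign_tiers(tier_row(census = TRUE, impact = "HIGH"))$tier, 3L)
  expect_equal(assign_tiers(tier_row())$tier, 4L)
  # synonymous in an oncogene is still Tier 5
  expect_equal(assign_tiers(tier_row(impact = "LOW", onc = TRUE))$tier, 5L)
  expect_equal(assign_tiers(tier_row(impact = "MODIFIER"))$tier, 5L)
  a <- assign_tiers(tier_row(hotspot = TRUE, em = ev_match("E", "gene")))
  expect_equal(a$tier, 2L)
  expect_setequal(a$rationale[[1]], c("EVIDENCE_CDE", "HOTSPOT_HOTSPOT"))
})

test_that("the packaged golden fixture reproduces its hand-written tiers", {
  b <- load_bundle(golden_dir())
  v <- suppressWarnings(
    read_somatic_vcf(file.path(golden_dir(), "golden.vcf")))
  expect_equal(nrow(v), 12L)
  expect_equal(attr(v, "n_filtered"), 1L)
  v <- assign_tiers(suppressWarnings(annotate_variants(v, b)))
  expected <- read.delim(file.path(golden_dir(), "expected_tiers.tsv"),
                         colClasses = c("character", "integer", "character",
                                        "character", "integer"))
  key <- paste(v$chrom, v$pos, v$ref, v$alt)
  got <- v$tier[match(paste(expected$chrom, expected$pos, expected$ref,
                            expected$alt), key)]
  expect_identical(got, expected$tier)
})

test_that("tiering partitions the variants and is permutation-invariant", {
  b <- shared_bundle()
  for (seed in c(5L, 6L)) {
    tv <- tiered_synthetic(b, seed, n_variants = 50L)
    expect_true(all(tv$tier %in% 1:5))
    expect_equal(sum(table(factor(tv$tier, levels = 1:5))), nrow(tv))
    perm <- withr::with_seed(seed, sample.int(nrow(tv)))
    tv2 <- assign_tiers(tv[perm, ])
    expect_equal(tv2$tier, tv$tier[perm])
  }
})

test_that("adding an A-level exact-allele match never worsens the tier", {
  b <- shared_bundle()
  tv <- tiered_synthetic(b, 31L, n_variants = 60L)
  boosted <- tv
  for (i in seq_len(nrow(boosted))) {
    em <- boosted$evidence_matches[[i]]
    boosted$evidence_matches[i] <- list(rbind(ev_match("A", "exact_allele",
                                                       id = "EVX"), em))
  }
  boosted <- assign_tiers(boosted)
  expect_true(all(boosted$tier <= tv$tier))
  expect_true(all(boosted$tier == 1L))
})

test_that("within-tier ranking follows evidence strength then literature score", {
  v <- rbind(tier_row(em = ev_match("B", "exact_allele"), gene = "GB"),
             tier_row(em = ev_match("A", "exact_allele"), gene = "GA"),
             tier_row(onc = TRUE, score = 0.2, gene = "GLO"),
             tier_row(onc = TRUE, score = 0.8, gene = "GHI"))
  r <- rank_within_tiers(assign_tiers(v))
  expect_equal(r$gene_symbol, c("GA", "GB", "GHI", "GLO"))
  expect_equal(r$rank_in_tier, c(1L, 2L, 1L, 2L))
  # level A before B within tier 1; higher literature score first in tier 3
  expect_equal(r$tier, c(1L, 1L, 3L, 3L))
})

test_that("ranking is stable: identical keys keep input order", {
  v <- rbind(tier_row(gene = "G1", pos = 10L), tier_row(gene = "G1", pos = 10L))
  v$marker <- c("first", "second")
  r <- rank_within_tiers(assign_tiers(v))
  expect_equal(r$marker, c("first", "second"))
})
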