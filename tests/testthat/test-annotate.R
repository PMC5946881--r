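test_that("protein positions parse from one- and three-letter HGVSp", {
  expect_equal(parse_protein_position("p.V600E"),
               list(ref_aa = "V", position = 600L))
  expect_equal(parse_protein_position("p.Gly12Asp"),
               list(ref_aa = "G", position = 12L))
  expect_equal(parse_protein_position("ENSP0001:p.Arg97*"),
               list(ref_aa = "R", position = 97L))
  expect_null(parse_protein_position(""))
  expect_null(parse_protein_position(NA_character_))
  expect_null(parse_protein_position("c.35G>A"))
})

test_that("consensus pathogenicity follows the two-thirds rule", {
  cp <- oncotier:::consensus_pathogenicity
  expect_equal(cp(character(0))$label, "unknown")
  expect_equal(cp(c("damaging", "damaging", "tolerated"))$label, "damaging")
  expect_equal(cp(c("damaging", "tolerated", "tolerated"))$label, "mixed")
  expect_equal(cp(c("tolerated", "tolerated"))$label, "tolerated")
  expect_equal(cp("damaging")$label, "mixed")  # single algorithm never damaging
})

test_that("every bundle evidence allele present in the VCF is re-discovered (closure)", {
  b <- shared_bundle()
  ev <- b$evidence[b$evidence$has_allele, ]
  v <- data.frame(chrom = ev$chrom, pos = ev$pos, ref = ev$ref, alt = ev$alt,
                  variant_class = variant_class_of(ev$ref, ev$alt),
                  gene_symbol = ev$gene_symbol,
                  transcript_id = paste0("TX_", ev$gene_symbol),
                  consequence = "missense_variant", hgvsp = "", hgvsc = "",
                  impact = "MODERATE", stringsAsFactors = FALSE)
  ann <- annotate_variants(v, b)
  for (i in seq_len(nrow(ann))) {
    em <- ann$evidence_matches[[i]]
    expect_false(is.null(em))
    expect_true(ev$id[i] %in%
                em$evidence_id[em$granularity == "exact_allele"])
  }
})

test_that("a VCF disjoint from the bundle produces zero exact matches (soundness)", {
  b <- shared_bundle()
  vcf <- tempfile(fileext = ".vcf")
  simulate_somatic_vcf(b, vcf, seed = 9L, n_variants = 80L,
                       disjoint_from_bundle = TRUE, hotspot_fraction = 0)
  ann <- suppressWarnings(annotate_variants(read_somatic_vcf(vcf), b))
  n_exact <- sum(vapply(ann$evidence_matches, function(e)
    if (is.null(e)) 0L else sum(e$granularity == "exact_allele"), integer(1)))
  expect_equal(n_exact, 0L)
})

test_that("codon-level hotspot overlap works through the HGVSp parse", {
  b <- shared_bundle()
  h <- b$hotspots[1, ]
  g <- b$genes[match(h$gene_symbol, b$genes$gene_symbol), ]
  pos <- g$span_start + 5L
  ref <- oncotier:::genome_base(b$genome, g$chrom, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  hgvsp <- paste0("p.", h$ref_aa, h$protein_position, "L")
  # independent oracle: the fixture string must itself parse by regex
  expect_true(grepl(paste0("^p\\.", h$ref_aa, h$protein_position), hgvsp))
  v <- data.frame(chrom = g$chrom, pos = pos, ref = ref, alt = alt,
                  variant_class = "SNV", gene_symbol = h$gene_symbol,
                  transcript_id = "TX", consequence = "missense_variant",
                  hgvsp = hgvsp, hgvsc = "", impact = "MODERATE",
                  stringsAsFactors = FALSE)
  ann <- annotate_variants(v, b)
  expect_true(ann$hotspot_overlap[1])
  expect_match(ann$hotspot_source[1], h$source)
  # an indel at the same codon must not hotspot-match
  v$variant_class <- "deletion"
  v$ref <- paste0(ref, "A")
  expect_false(annotate_variants(v, b)$hotspot_overlap[1])
})

test_that("annotation is pure and order-invariant", {
  b <- shared_bundle()
  vcf <- tempfile(fileext = ".vcf")
  simulate_somatic_vcf(b, vcf, seed = 21L, n_variants = 40L)
  v <- suppressWarnings(read_somatic_vcf(vcf))
  a1 <- suppressWarnings(annotate_variants(v, b))
  perm <- withr::with_seed(1L, sample.int(nrow(v)))
  a2 <- suppressWarnings(annotate_variants(v[perm, ], b))
  a2 <- a2[order(perm), ]
  rownames(a2) <- NULL
  expect_equal(a1$evidence_matches, a2$evidence_matches)
  expect_equal(a1$hotspot_overlap, a2$hotspot_overlap)
  expect_equal(a1$patho_label, a2$patho_label)
  expect_equal(a1$literature_score, a2$literature_score)
})

test_that("unknown gene symbols warn and get empty gene records", {
  b <- shared_bundle()
  v <- data.frame(chrom = "1", pos = 500L,
                  ref = oncotier:::genome_base(b$genome, "1", 500L),
                  alt = "A", variant_class = "SNV", gene_symbol = "NOSUCH",
                  transcript_id = "TX", consequence = "missense_variant",
                  hgvsp = "", hgvsc = "", impact = "MODERATE",
                  stringsAsFactors = FALSE)
  if (v$alt == v$ref) v$alt <- "C"
  expect_warning(ann <- annotate_variants(v, b), "NOSUCH")
  expect_false(ann$gene_known[1])
  expect_equal(ann$literature_score[1], 0)
})

test_that("gene aggregation sorts by score then symbol", {
  ann <- data.frame(gene_symbol = c("B", "A", "C", "A"),
                    stringsAsFactors = FALSE)
  ann$is_oncogene <- c(TRUE, FALSE, FALSE, FALSE)
  ann$is_tsg <- FALSE
  ann$in_census <- FALSE
  ann$literature_score <- c(0.4, 0.9, 0.4, 0.9)
  ann$gene_drugs <- ""
  tab <- aggregate_gene_level(ann)
  expect_equal(tab$gene_symbol, c("A", "B", "C"))  # 0.9 first, then tie B<C
  expect_equal(tab$n_variants, c(2L, 1L, 1L))
  expect_equal(nrow(aggregate_gene_level(ann[0, ])), 0L)
})
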