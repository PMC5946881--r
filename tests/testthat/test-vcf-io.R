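make_vcf <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: Allele|Consequence|IMPACT|SYMBOL|Feature|",
           "HGVSc|HGVSp|CANONICAL|PICK\">"),
    "##contig=<ID=1,length=10000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body), path)
  path
}
csq <- function(allele, cons = "missense_variant", impact = "MODERATE",
                sym = "G1", tx = "TX1", pick = "1")
  paste(allele, cons, impact, sym, tx, "", "", "", pick, sep = "|")

test_that("an empty VCF yields an empty variant table", {
  v <- read_somatic_vcf(make_vcf(character(0)))
  expect_equal(nrow(v), 0L)
  expect_equal(attr(v, "n_filtered"), 0L)
})

test_that("non-PASS records are excluded and counted", {
  p <- make_vcf(c(
    paste("1", 100, ".", "A", "T", ".", "PASS",
          paste0("CSQ=", csq("T")), sep = "\t"),
    paste("1", 200, ".", "C", "G", ".", ".",
          paste0("CSQ=", csq("G")), sep = "\t"),
    paste("1", 300, ".", "G", "A", ".", "LowQual",
          paste0("CSQ=", csq("A")), sep = "\t")))
  v <- read_somatic_vcf(p)
  expect_equal(nrow(v), 2L)
  expect_equal(attr(v, "n_filtered"), 1L)
  expect_equal(nrow(read_somatic_vcf(p, retain_nonpass = TRUE)), 3L)
})

test_that("alleles are normalized on read (shared prefix/suffix trimmed)", {
  p <- make_vcf(paste("1", 100, ".", "CAG", "CTG", ".", "PASS",
                      paste0("CSQ=", csq("CTG")), sep = "\t"))
  v <- read_somatic_vcf(p)
  expect_equal(v$pos, 101L)
  expect_equal(v$ref, "A")
  expect_equal(v$alt, "T")
  expect_equal(v$variant_class, "SNV")
})

test_that("missing CSQ, multiple picks, and multi-sample input are hard errors", {
  expect_error(read_somatic_vcf(make_vcf(
    paste("1", 100, ".", "A", "T", ".", "PASS", "DP=10", sep = "\t"))),
    "no CSQ INFO field")
  expect_error(read_somatic_vcf(make_vcf(
    paste("1", 100, ".", "A", "T", ".", "PASS",
          paste0("CSQ=", csq("T"), ",", csq("T", tx = "TX2")), sep = "\t"))),
    "expected exactly one")
  # two sample columns
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    paste("1", 100, ".", "A", "T", ".", "PASS",
          paste0("CSQ=", csq("T")), "GT", "0/1", "0/1", sep = "\t")), p)
  expect_error(read_somatic_vcf(p), "single-sample")
})

test_that("fallback pick ranking uses impact, canonical flag, transcript id", {
  blocks <- paste0("CSQ=",
    paste("T", "intron_variant", "MODIFIER", "G1", "TX3", "", "", "", "",
          sep = "|"), ",",
    paste("T", "missense_variant", "MODERATE", "G1", "TX2", "", "", "", "",
          sep = "|"), ",",
    paste("T", "missense_variant", "MODERATE", "G1", "TX1", "", "", "", "",
          sep = "|"))
  v <- read_somatic_vcf(make_vcf(
    paste("1", 100, ".", "A", "T", ".", "PASS", blocks, sep = "\t")))
  expect_equal(v$impact, "MODERATE")
  expect_equal(v$transcript_id, "TX1")  # lexicographic tie-break
})

test_that("multi-allelic records split into the same variants as separate records", {
  multi <- make_vcf(paste("1", 100, ".", "A", "T,G", ".", "PASS",
                          paste0("CSQ=", csq("T"), ",", csq("G", sym = "G2")),
                          sep = "\t"))
  sep1 <- make_vcf(c(
    paste("1", 100, ".", "A", "T", ".", "PASS", paste0("CSQ=", csq("T")),
          sep = "\t"),
    paste("1", 100, ".", "A", "G", ".", "PASS",
          paste0("CSQ=", csq("G", sym = "G2")), sep = "\t")))
  vm <- read_somatic_vcf(multi)
  vs <- read_somatic_vcf(sep1)
  cols <- c("chrom", "pos", "ref", "alt", "variant_class", "gene_symbol")
  expect_equal(vm[cols], vs[cols])
})

test_that("write/read round-trips normalized variants exactly", {
  b <- shared_bundle()
  vcf <- tempfile(fileext = ".vcf")
  truth <- simulate_somatic_vcf(b, vcf, seed = 3L, n_variants = 60L,
                                indel_fraction = 0.2)
  v <- read_somatic_vcf(vcf)
  expect_equal(nrow(v), 60L)
  p2 <- tempfile(fileext = ".vcf")
  write_somatic_vcf(v, p2)
  v2 <- read_somatic_vcf(p2)
  expect_equal(v2[c("chrom", "pos", "ref", "alt")],
               v[c("chrom", "pos", "ref", "alt")])
})

test_that("chr prefixes are stripped on ingest", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste("chr7", 100, ".", "A", "T", ".", "PASS",
          paste0("CSQ=", csq("T")), sep = "\t")), p)
  expect_equal(read_somatic_vcf(p)$chrom, "7")
})
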