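# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; the only packaged fixture is the hand-designed golden
# bundle under extdata/golden.

.fixture_env <- new.env(parent = emptyenv())

golden_dir <- function() {
  d <- system.file("extdata", "golden", package = "oncotier")
  if (d == "") stop("golden fixture not installed")
  d
}

# one medium synthetic bundle shared across tests (built once per session)
shared_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    dir <- file.path(tempdir(), "oncotier-shared-bundle")
    if (!dir.exists(dir))
      generate_fixture_bundle(dir, seed = 101L, n_genes = 20L,
                              n_evidence = 50L, n_hotspots = 15L,
                              k_signatures = 4L, genome_length = 100000L)
    .fixture_env$bundle <- load_bundle(dir)
  }
  .fixture_env$bundle
}

# independent trim oracle: enumerate every legal (prefix, suffix) trim and
# return all minimal anchored forms; the engine's answer must be the
# leftmost (suffix-first) of those
trim_oracle <- function(pos, ref, alt) {
  forms <- list()
  for (p in 0:(min(nchar(ref), nchar(alt)) - 1L)) {
    if (p > 0 && substr(ref, 1, p) != substr(alt, 1, p)) break
    rr <- substring(ref, p + 1L)
    aa <- substring(alt, p + 1L)
    for (s in 0:(min(nchar(rr), nchar(aa)) - 1L)) {
      if (s > 0 && (substr(rr, nchar(rr) - s + 1L, nchar(rr)) !=
                    substr(aa, nchar(aa) - s + 1L, nchar(aa)))) break
      forms[[length(forms) + 1L]] <- list(
        pos = pos + p,
        ref = substr(rr, 1L, nchar(rr) - s),
        alt = substr(aa, 1L, nchar(aa) - s))
    }
  }
  forms <- Filter(function(f) f$ref != f$alt, forms)
  lens <- vapply(forms, function(f) nchar(f$ref) + nchar(f$alt), numeric(1))
  minimal <- forms[lens == min(lens)]
  poss <- vapply(minimal, function(f) f$pos, numeric(1))
  minimal[[which.min(poss)]]
}

random_allele_triple <- function() {
  bases <- c("A", "C", "G", "T")
  repeat {
    ref <- paste(sample(bases, sample.int(4L, 1L), replace = TRUE),
                 collapse = "")
    alt <- paste(sample(bases, sample.int(4L, 1L), replace = TRUE),
                 collapse = "")
    if (ref != alt) return(list(pos = sample.int(1000L, 1L), ref = ref,
                                alt = alt))
  }
}

# brute-force all-pairs inclusive-coordinate overlap scan (CNA oracle)
brute_force_overlap <- function(segments, genes) {
  out <- list()
  for (i in seq_len(nrow(segments))) {
    for (j in seq_len(nrow(genes))) {
      if (segments$chrom[i] != genes$chrom[j]) next
      lo <- max(segments$start[i], genes$span_start[j])
      hi <- min(segments$end[i], genes$span_end[j])
      if (lo <= hi)
        out[[length(out) + 1L]] <- data.frame(
          seg = i, gene = genes$gene_symbol[j], overlap_bp = hi - lo + 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(seg = integer(), gene = character(),
                  overlap_bp = integer(), stringsAsFactors = FALSE)
}

# run the full pipeline on one simulated tumor; returns run_report() output
run_synthetic <- function(bundle, seed, n_variants = 200L, outdir = NULL,
                          with_cna = TRUE, ...) {
  vcf <- tempfile(fileext = ".vcf")
  simulate_somatic_vcf(bundle, vcf, seed = seed, n_variants = n_variants)
  cna <- NULL
  if (with_cna) {
    cna <- tempfile(fileext = ".tsv")
    simulate_cna_file(bundle, cna, seed = seed + 1L)
  }
  if (is.null(outdir)) outdir <- tempfile("out")
  rc <- run_config(vcf, bundle$dir, "SYNTH", outdir, input_cna = cna, ...)
  run_report(rc, quiet = TRUE)
}

# annotate + tier a freshly simulated VCF without rendering
tiered_synthetic <- function(bundle, seed, n_variants = 40L, ...) {
  vcf <- tempfile(fileext = ".vcf")
  simulate_somatic_vcf(bundle, vcf, seed = seed, n_variants = n_variants, ...)
  v <- suppressWarnings(read_somatic_vcf(vcf))
  assign_tiers(suppressWarnings(annotate_variants(v, bundle)))
}
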