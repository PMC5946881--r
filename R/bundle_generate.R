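#' Generate a deterministic synthetic knowledge bundle
#'
#' Builds a complete, internally consistent bundle directory for testing and
#' demonstration: a uniform-ACGT genome, genes with pairwise non-overlapping
#' transcript spans, evidence/hotspot/frequency/pathogenicity tables whose
#' allele keys fall inside gene spans and agree with the genome's reference
#' bases, Dirichlet-drawn reference signatures, and a trained MSI classifier.
#' Output is byte-identical for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling every random choice.
#' @param n_genes Number of genes (each with one transcript span).
#' @param n_evidence Number of clinical evidence items (~20% gene-level).
#' @param n_hotspots Number of hotspot/driver codon records.
#' @param k_signatures Number of reference signatures (max 10).
#' @param genome_length Genome size in bp (single contig named "1").
#' @param separated_signatures If TRUE, signatures get disjoint context
#'   supports (well-separated; used for recovery experiments).
#' @param with_msi_model Train and serialize an MSI classifier into the
#'   bundle (default TRUE).
#' @return `dir`, invisibly.
#' @export
generate_fixture_bundle <- function(dir, seed, n_genes = 25L, n_evidence = 60L,
                                    n_hotspots = 20L, k_signatures = 4L,
                                    genome_length = 200000L,
                                    separated_signatures = FALSE,
                                    with_msi_model = TRUE) {
  stopifnot(n_genes > 0L, n_evidence > 0L, n_hotspots > 0L,
            k_signatures > 0L, k_signatures <= 10L, genome_length > 0L)
  slot <- genome_length %/% n_genes
  if (slot < 300L)
    stop("genome of ", genome_length, " bp is too short to host ", n_genes,
         " genes", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bases <- c("A", "C", "G", "T")

  withr::with_seed(seed, {
    ## genome: one contig, uniform ACGT
    chars <- sample(bases, genome_length, replace = TRUE)
    seqstr <- paste(chars, collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(seqstr, "1"))
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fa, width = 60L)
    if (file.exists(paste0(fa, ".fai"))) file.remove(paste0(fa, ".fai"))
    Rsamtools::indexFa(fa)

    ## genes: one non-overlapping span per slot
    lens <- pmax(200L, as.integer(round(slot * stats::runif(n_genes, 0.3, 0.6))))
    offs <- vapply(seq_len(n_genes), function(i)
      sample.int(slot - lens[i] - 1L, 1L), integer(1))
    starts <- (seq_len(n_genes) - 1L) * slot + offs
    n_onc <- stats::runif(n_genes) < 0.3
    n_tsg <- !n_onc & stats::runif(n_genes) < 0.3
    census <- n_onc | n_tsg | stats::runif(n_genes) < 0.1
    drugs <- vapply(seq_len(n_genes), function(i) {
      if (stats::runif(1) < 0.3)
        paste(sample(paste0("DRUG_", LETTERS[1:12]),
                     sample.int(2L, 1L)), collapse = ",")
      else "."
    }, character(1))
    genes <- data.frame(
      gene_symbol = sprintf("GENE%03d", seq_len(n_genes)),
      is_oncogene = as.integer(n_onc), is_tsg = as.integer(n_tsg),
      in_cancer_gene_census = as.integer(census),
      literature_score = round(stats::runif(n_genes), 4),
      drugs = drugs, chrom = "1",
      span_start = starts, span_end = starts + lens - 1L,
      stringsAsFactors = FALSE)

    ## evidence: ~80% allele-level keys inside gene spans
    ev <- lapply(seq_len(n_evidence), function(i) {
      g <- sample.int(n_genes, 1L)
      typ <- sample(c("diagnostic", "prognostic", "predisposing", "predictive"),
                    1L, prob = c(0.2, 0.25, 0.15, 0.4))
      lvl <- sample(c("A", "B", "C", "D", "E"), 1L,
                    prob = c(0.1, 0.15, 0.3, 0.25, 0.2))
      drug <- if (typ == "predictive")
        sample(paste0("DRUG_", LETTERS[1:12]), 1L) else "."
      tt <- sample(c("breast", "colorectal", "lung", "melanoma", "any"), 1L)
      gene_level <- stats::runif(1) < 0.2
      ppos <- "."
      raa <- "."
      if (gene_level) {
        chrom <- "."; pos <- "."; ref <- "."; alt <- "."
      } else {
        chrom <- "1"
        pos <- sample(seq(genes$span_start[g] + 1L, genes$span_end[g] - 1L), 1L)
        ref <- chars[pos]
        if (stats::runif(1) < 0.9) {          # SNV
          alt <- sample(setdiff(bases, ref), 1L)
        } else if (stats::runif(1) < 0.5) {   # insertion
          alt <- paste0(ref, sample(bases, 1L))
        } else {                              # deletion
          ref <- paste0(chars[pos], chars[pos + 1L])
          alt <- chars[pos]
        }
        if (stats::runif(1) < 0.3) {          # codon-level extra key
          ppos <- sample.int(800L, 1L)
          raa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 1L)
        }
      }
      data.frame(id = sprintf("EV%04d", i), chrom = chrom, pos = pos,
                 ref = ref, alt = alt, gene_symbol = genes$gene_symbol[g],
                 evidence_type = typ,
                 clinical_significance = switch(typ,
                   predictive = sample(c("sensitivity", "resistance"), 1L),
                   prognostic = sample(c("poor outcome", "good outcome"), 1L),
                   "positive"),
                 evidence_level = lvl, tumor_type = tt, drug = drug,
                 citation = sprintf("PMID:%07d", sample.int(9999999L, 1L)),
                 protein_position = ppos, ref_aa = raa,
                 stringsAsFactors = FALSE)
    })
    evidence <- do.call(rbind, ev)

    ## hotspots
    hotspots <- data.frame(
      gene_symbol = genes$gene_symbol[sample.int(n_genes, n_hotspots,
                                                 replace = TRUE)],
      protein_position = sample.int(800L, n_hotspots, replace = TRUE),
      ref_aa = sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n_hotspots,
                      replace = TRUE),
      source = sample(c("hotspot", "predicted_driver", "curated_mutation"),
                      n_hotspots, replace = TRUE),
      stringsAsFactors = FALSE)

    ## frequencies + pathogenicity over allele-level evidence keys
    ak <- evidence[evidence$ref != ".", , drop = FALSE]
    fr_rows <- ak[sample.int(nrow(ak), min(nrow(ak), n_evidence %/% 2L)), ,
                  drop = FALSE]
    cohort <- sample(100:2000, nrow(fr_rows), replace = TRUE)
    freqs <- data.frame(
      chrom = fr_rows$chrom, pos = fr_rows$pos, ref = fr_rows$ref,
      alt = fr_rows$alt,
      tumor_type = sample(c("breast", "colorectal", "lung", "melanoma"),
                          nrow(fr_rows), replace = TRUE),
      count = vapply(cohort, function(n) sample.int(n, 1L), integer(1)),
      cohort_size = cohort, stringsAsFactors = FALSE)

    pt_rows <- ak[sample.int(nrow(ak), min(nrow(ak), n_evidence %/% 2L)), ,
                  drop = FALSE]
    patho <- do.call(rbind, lapply(seq_len(nrow(pt_rows)), function(i) {
      algs <- sample(c("sift_like", "polyphen_like", "cadd_like"),
                     sample.int(3L, 1L))
      data.frame(chrom = pt_rows$chrom[i], pos = pt_rows$pos[i],
                 ref = pt_rows$ref[i], alt = pt_rows$alt[i],
                 algorithm = algs, score = round(stats::runif(length(algs)), 3),
                 call = sample(c("damaging", "tolerated", "unknown"),
                               length(algs), replace = TRUE,
                               prob = c(0.45, 0.45, 0.1)),
                 stringsAsFactors = FALSE)
    }))

    ## signatures
    W <- random_signature_matrix(k_signatures, separated = separated_signatures)
    sigtab <- data.frame(context = mutation_context_classes(),
                         round(W, 8), check.names = FALSE,
                         stringsAsFactors = FALSE)
    # re-normalize after rounding so columns sum to exactly 1
    for (j in seq_len(k_signatures) + 1L)
      sigtab[[j]] <- sigtab[[j]] / sum(sigtab[[j]])
    aet <- sample(c("UV-like", "smoking-like", "deamination-like",
                    "MMR-deficiency-like", "unknown"),
                  k_signatures, replace = TRUE)

    wt <- function(d, f) utils::write.table(
      d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(genes, "genes.tsv")
    wt(evidence, "evidence.tsv")
    wt(hotspots, "hotspots.tsv")
    wt(freqs, "variant_frequencies.tsv")
    wt(patho, "pathogenicity.tsv")
    utils::write.table(
      format(sigtab, digits = 15, scientific = FALSE, trim = TRUE),
      file.path(dir, "signatures.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

    if (with_msi_model) {
      cohort_df <- simulate_msi_cohort(300L, 300L,
                                       seed = (seed %% 100000L) + 17L)
      model <- train_msi_model(cohort_df)
      msi_model_to_json(model, file.path(dir, "msi_model.json"))
    }

    manifest <- list(
      bundle_version = paste0("synthetic-", seed, "-v1"),
      genome_build = "synthetic",
      files = list(genes.tsv = nrow(genes), evidence.tsv = nrow(evidence),
                   hotspots.tsv = nrow(hotspots),
                   variant_frequencies.tsv = nrow(freqs),
                   pathogenicity.tsv = nrow(patho),
                   signatures.tsv = 96L),
      signature_aetiologies = as.list(stats::setNames(aet, colnames(W))))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(dir)
}

#' Draw a random reference-signature matrix
#'
#' Each signature is a Dirichlet-like draw over the 96 contexts (independent
#' gamma variates normalized to sum 1). With `separated = TRUE` each
#' signature is supported on its own disjoint block of contexts, giving
#' well-separated signatures for parameter-recovery experiments.
#'
#' @param k Number of signatures.
#' @param concentration Dirichlet concentration parameter (default 0.3).
#' @param separated Disjoint supports (default FALSE).
#' @return 96 x k matrix with canonical context rownames, columns `SIG1..k`
#'   each summing to 1.
#' @export
random_signature_matrix <- function(k, concentration = 0.3, separated = FALSE) {
  ctx <- mutation_context_classes()
  W <- matrix(0, 96L, k, dimnames = list(ctx, paste0("SIG", seq_len(k))))
  if (separated) {
    blocks <- split(sample(96L), rep(seq_len(k), length.out = 96L))
    for (j in seq_len(k)) {
      g <- stats::rgamma(length(blocks[[j]]), shape = 1)
      W[blocks[[j]], j] <- g / sum(g)
    }
  } else {
    for (j in seq_len(k)) {
      g <- stats::rgamma(96L, shape = concentration)
      W[, j] <- g / sum(g)
    }
  }
  W
}
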