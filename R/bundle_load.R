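#' Load and validate a knowledge bundle directory
#'
#' The bundle is the versioned set of reference tables every annotation join
#' draws from. It is plain TSV + FASTA so that it is transparent, diffable
#' and trivially generatable:
#' \itemize{
#'   \item `genes.tsv` — one row per transcript span with gene-level oncology
#'     facts (oncogene/TSG/census flags, literature association score in
#'     `[0,1]`, antineoplastic drugs).
#'   \item `evidence.tsv` — curated clinical assertions (diagnostic,
#'     prognostic, predisposing, predictive), graded A–E, keyed by a full
#'     normalized allele, by gene + protein position (codon-level), or by
#'     gene symbol alone.
#'   \item `hotspots.tsv` — recurrently mutated codons and predicted drivers.
#'   \item `variant_frequencies.tsv` — tumor-type frequencies of previously
#'     observed somatic alleles.
#'   \item `pathogenicity.tsv` — per-algorithm pathogenicity calls.
#'   \item `signatures.tsv` — reference mutational signatures: 96 rows in
#'     canonical context order, one column per signature, each summing to 1.
#'   \item `genome.fa` (+`.fai`) — the reference sequence.
#'   \item `manifest.json` — bundle version, per-file row counts, signature
#'     aetiologies.
#'   \item `msi_model.json` — optional serialized MSI classifier.
#' }
#' All invariants are validated at load; allele keys are re-normalized with
#' [normalize_allele()] and checked against the genome's reference bases.
#'
#' @param dir Bundle directory path.
#' @return An object of class `oncotier_bundle`.
#' @export
load_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("bundle directory not found: ", dir, call. = FALSE)
  need <- c("genes.tsv", "evidence.tsv", "hotspots.tsv",
            "variant_frequencies.tsv", "pathogenicity.tsv", "signatures.tsv",
            "genome.fa", "manifest.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("bundle is missing file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  # everything as character: single-letter allele columns must never be
  # type-guessed into logicals
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE,
                                      na.strings = NULL,
                                      colClasses = "character")
  genes <- rd("genes.tsv")
  evidence <- rd("evidence.tsv")
  hotspots <- rd("hotspots.tsv")
  freqs <- rd("variant_frequencies.tsv")
  patho <- rd("pathogenicity.tsv")
  sigtab <- rd("signatures.tsv")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))

  fail <- function(file, line, msg)
    stop("bundle invariant violated in ", file, " line ", line + 1L, ": ", msg,
         call. = FALSE)

  # -- genes
  genes$is_oncogene <- as.logical(as.integer(genes$is_oncogene))
  genes$is_tsg <- as.logical(as.integer(genes$is_tsg))
  genes$in_cancer_gene_census <- as.logical(as.integer(genes$in_cancer_gene_census))
  genes$literature_score <- as.numeric(genes$literature_score)
  genes$span_start <- as.integer(genes$span_start)
  genes$span_end <- as.integer(genes$span_end)
  genes$chrom <- normalize_chrom(genes$chrom)
  bad <- which(is.na(genes$literature_score) | genes$literature_score < 0 |
               genes$literature_score > 1)
  if (length(bad)) fail("genes.tsv", bad[1], "literature_score outside [0,1]")
  bad <- which(genes$span_start > genes$span_end | genes$span_start < 1L)
  if (length(bad)) fail("genes.tsv", bad[1], "malformed transcript span")

  # -- evidence
  evidence$pos <- suppressWarnings(as.integer(evidence$pos))
  evidence$protein_position <- suppressWarnings(as.integer(evidence$protein_position))
  evidence$chrom <- normalize_chrom(evidence$chrom)
  bad <- which(!evidence$evidence_level %in% c("A", "B", "C", "D", "E"))
  if (length(bad))
    fail("evidence.tsv", bad[1],
         paste0("evidence_level '", evidence$evidence_level[bad[1]],
                "' not in A-E"))
  bad <- which(!evidence$evidence_type %in%
               c("diagnostic", "prognostic", "predisposing", "predictive"))
  if (length(bad)) fail("evidence.tsv", bad[1], "unknown evidence_type")
  bad <- which(evidence$evidence_type == "predictive" &
               (is.na(evidence$drug) | evidence$drug %in% c("", ".")))
  if (length(bad))
    fail("evidence.tsv", bad[1], "predictive item carries no drug")
  has_allele <- !(evidence$ref %in% c("", ".")) & !is.na(evidence$pos)
  for (j in which(has_allele)) {
    nm <- normalize_allele(evidence$pos[j], evidence$ref[j], evidence$alt[j])
    evidence$pos[j] <- nm$pos
    evidence$ref[j] <- nm$ref
    evidence$alt[j] <- nm$alt
    gbase <- genome_base(genome, evidence$chrom[j], nm$pos)
    if (!identical(gbase, substr(nm$ref, 1L, 1L)))
      fail("evidence.tsv", j, paste0("allele ref does not match genome at ",
                                     evidence$chrom[j], ":", nm$pos))
  }
  evidence$has_allele <- has_allele

  # -- hotspots
  hotspots$protein_position <- as.integer(hotspots$protein_position)
  bad <- which(is.na(hotspots$protein_position) | hotspots$protein_position < 1L)
  if (length(bad)) fail("hotspots.tsv", bad[1], "protein_position < 1")
  bad <- which(!hotspots$source %in%
               c("hotspot", "predicted_driver", "curated_mutation"))
  if (length(bad)) fail("hotspots.tsv", bad[1], "unknown hotspot source")

  # -- frequencies
  freqs$pos <- as.integer(freqs$pos)
  freqs$count <- as.integer(freqs$count)
  freqs$cohort_size <- as.integer(freqs$cohort_size)
  freqs$chrom <- normalize_chrom(freqs$chrom)
  bad <- which(is.na(freqs$count) | freqs$count < 0L |
               is.na(freqs$cohort_size) | freqs$cohort_size < 1L |
               freqs$count > freqs$cohort_size)
  if (length(bad))
    fail("variant_frequencies.tsv", bad[1], "count/cohort_size malformed")
  for (j in seq_len(nrow(freqs))) {
    nm <- normalize_allele(freqs$pos[j], freqs$ref[j], freqs$alt[j])
    freqs$pos[j] <- nm$pos; freqs$ref[j] <- nm$ref; freqs$alt[j] <- nm$alt
  }

  # -- pathogenicity
  patho$pos <- as.integer(patho$pos)
  patho$score <- as.numeric(patho$score)
  patho$chrom <- normalize_chrom(patho$chrom)
  bad <- which(!patho$call %in% c("damaging", "tolerated", "unknown"))
  if (length(bad)) fail("pathogenicity.tsv", bad[1], "undefined call value")
  for (j in seq_len(nrow(patho))) {
    nm <- normalize_allele(patho$pos[j], patho$ref[j], patho$alt[j])
    patho$pos[j] <- nm$pos; patho$ref[j] <- nm$ref; patho$alt[j] <- nm$alt
  }

  # -- signatures
  if (nrow(sigtab) != 96L)
    stop("bundle invariant violated in signatures.tsv: expected 96 rows, got ",
         nrow(sigtab), call. = FALSE)
  if (!identical(sigtab[[1]], mutation_context_classes()))
    stop("bundle invariant violated in signatures.tsv: context column is not ",
         "in canonical order", call. = FALSE)
  W <- vapply(sigtab[-1], function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      stop("bundle invariant violated in signatures.tsv: non-numeric weight",
           call. = FALSE)
    v
  }, numeric(96L))
  rownames(W) <- sigtab[[1]]
  if (any(W < 0))
    stop("bundle invariant violated in signatures.tsv: negative weight",
         call. = FALSE)
  sums <- colSums(W)
  bad <- which(abs(sums - 1) > 1e-9)
  if (length(bad))
    stop("bundle invariant violated in signatures.tsv: column '",
         colnames(W)[bad[1]], "' sums to ", format(sums[bad[1]]),
         ", expected 1", call. = FALSE)
  aet <- unlist(manifest$signature_aetiologies)
  aetiologies <- stats::setNames(
    ifelse(colnames(W) %in% names(aet), aet[colnames(W)], "unknown"),
    colnames(W))
  signatures <- structure(
    list(matrix = W, contexts = rownames(W), aetiologies = aetiologies),
    class = "signature_matrix")

  msi_model <- NULL
  msi_path <- file.path(dir, "msi_model.json")
  if (file.exists(msi_path)) msi_model <- msi_model_from_json(msi_path)

  manifest$files <- list(
    genes.tsv = nrow(genes), evidence.tsv = nrow(evidence),
    hotspots.tsv = nrow(hotspots),
    variant_frequencies.tsv = nrow(freqs),
    pathogenicity.tsv = nrow(patho), signatures.tsv = nrow(sigtab))

  structure(
    list(dir = dir, genes = genes, evidence = evidence, hotspots = hotspots,
         frequencies = freqs, pathogenicity = patho, signatures = signatures,
         genome = genome, msi_model = msi_model, manifest = manifest),
    class = "oncotier_bundle")
}

genome_base <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome)) return(NA_character_)
  if (pos < 1L || pos > length(genome[[chrom]])) return(NA_character_)
  as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
}

#' @export
print.oncotier_bundle <- function(x, ...) {
  cat("Oncology knowledge bundle [",
      x$manifest$bundle_version %||% "unversioned", "]\n", sep = "")
  cat("  genes/transcripts: ", nrow(x$genes),
      "; evidence items: ", nrow(x$evidence),
      "; hotspots: ", nrow(x$hotspots), "\n", sep = "")
  cat("  signatures: ", ncol(x$signatures$matrix),
      "; genome contigs: ", length(x$genome),
      " (", sum(Biostrings::width(x$genome)), " bp)\n", sep = "")
  cat("  MSI model: ", if (is.null(x$msi_model)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}
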