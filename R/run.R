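#' Build and validate a run configuration
#'
#' Bundles the inputs, output location and all engine thresholds for one
#' end-to-end run. Referenced paths must exist at validation time.
#'
#' @param input_vcf Path to the somatic VCF.
#' @param bundle_dir Knowledge bundle directory.
#' @param sample_id Non-empty sample identifier.
#' @param output_dir Output directory.
#' @param input_cna Optional CNA segment TSV path.
#' @param enable_msi,enable_signatures Toggle the whole-profile analyses.
#' @param formats Output formats, subset of `c("json", "tsv", "html")`.
#' @param ... Threshold overrides passed to [default_config()].
#' @return List of class `run_config`.
#' @export
run_config <- function(input_vcf, bundle_dir, sample_id, output_dir,
                       input_cna = NULL, enable_msi = TRUE,
                       enable_signatures = TRUE,
                       formats = c("json", "tsv", "html"), ...) {
  if (!nzchar(sample_id)) stop("sample_id must be non-empty", call. = FALSE)
  if (!file.exists(input_vcf))
    stop("input VCF not found: ", input_vcf, call. = FALSE)
  if (!dir.exists(bundle_dir))
    stop("bundle directory not found: ", bundle_dir, call. = FALSE)
  if (!is.null(input_cna) && !file.exists(input_cna))
    stop("CNA segment file not found: ", input_cna, call. = FALSE)
  structure(list(input_vcf = input_vcf, input_cna = input_cna,
                 bundle_dir = bundle_dir, sample_id = sample_id,
                 output_dir = output_dir, enable_msi = enable_msi,
                 enable_signatures = enable_signatures, formats = formats,
                 config = default_config(...)),
            class = "run_config")
}

#' Run the interpretation pipeline end-to-end
#'
#' Executes the stages in order — read, annotate, tier, whole-profile
#' measures (catalog + signatures, MSI, TMB), CNA intersection, report
#' assembly and rendering — logging per-stage counts and timings to stderr.
#' Output files carry no timestamps, so identical inputs and configuration
#' produce byte-identical files across runs.
#'
#' @param rc A `run_config` ([run_config()]).
#' @param quiet Suppress the stage log (default FALSE).
#' @return Invisibly, a list with the `tier_report` and the written `files`.
#' @export
run_report <- function(rc, quiet = FALSE) {
  stopifnot(inherits(rc, "run_config"))
  cfg <- rc$config
  t0 <- proc.time()[["elapsed"]]
  log <- function(stage, msg) {
    if (!quiet)
      message(sprintf("[%s] %s (%.2fs)", stage, msg,
                      proc.time()[["elapsed"]] - t0))
  }

  bundle <- load_bundle(rc$bundle_dir)
  log("bundle", paste0("loaded '", bundle$manifest$bundle_version, "'"))

  variants <- read_somatic_vcf(rc$input_vcf,
                               csq_subfields = cfg$csq_subfields,
                               csq_field = cfg$csq_field_name,
                               retain_nonpass = cfg$retain_nonpass)
  n_filtered <- attr(variants, "n_filtered")
  log("read", paste0(nrow(variants), " PASS variants (", n_filtered,
                     " records excluded by FILTER)"))

  variants <- annotate_variants(variants, bundle, cfg)
  log("annotate", paste0(sum(vapply(variants$evidence_matches, function(e)
    !is.null(e), logical(1))), " variants with evidence matches"))

  variants <- assign_tiers(variants, cfg)
  variants <- rank_within_tiers(variants)
  log("tier", paste(sprintf("T%d:%d", 1:5,
                            vapply(1:5, function(t) sum(variants$tier == t),
                                   integer(1))), collapse = " "))

  signature_fit <- NULL
  if (rc$enable_signatures) {
    catalog <- build_catalog(variants, bundle$genome)
    if (catalog$n_snvs_used > 0L) {
      signature_fit <- fit_signatures(catalog, bundle$signatures,
                                      prune_threshold = cfg$sig_prune_threshold,
                                      min_mutations = cfg$sig_min_mutations)
      log("signatures", paste0(length(signature_fit$fractions),
                               " signatures retained, cosine ",
                               round(signature_fit$reconstruction_cosine, 3)))
    } else {
      log("signatures", "skipped: no SNVs in catalog")
    }
  }

  msi_prediction <- NULL
  if (rc$enable_msi) {
    if (is.null(bundle$msi_model))
      stop("MSI prediction enabled but the bundle carries no msi_model.json",
           call. = FALSE)
    msi_prediction <- predict_msi(variants, cfg$tmb_target_size_mb,
                                  bundle$msi_model,
                                  min_variants = cfg$msi_min_variants)
    log("msi", msi_prediction$status)
  }

  tmb_result <- compute_tmb(variants, cfg$tmb_target_size_mb)
  log("tmb", paste0(format(tmb_result$tmb, digits = 4), " mut/Mb"))

  cna_events <- NULL
  cna_segments <- NULL
  if (!is.null(rc$input_cna)) {
    cna_segments <- read_cna_segments(rc$input_cna)
    cna_segments <- call_segments(cna_segments,
                                  gain_log2 = cfg$cna_gain_log2,
                                  loss_log2 = cfg$cna_loss_log2)
    cna_events <- intersect_genes(cna_segments, bundle)
    log("cna", paste0(nrow(cna_events), " gene events from ",
                      nrow(cna_segments), " segments"))
  }

  report <- build_report(rc$sample_id, variants,
                         aggregate_gene_level(variants),
                         cna_events = cna_events, cna_segments = cna_segments,
                         signature_fit = signature_fit,
                         msi_prediction = msi_prediction,
                         tmb_result = tmb_result, bundle = bundle,
                         config = cfg, n_filtered = n_filtered)
  files <- render_report(report, formats = rc$formats, outdir = rc$output_dir)
  log("report", paste0(length(files), " files written to ", rc$output_dir))
  invisible(list(report = report, files = files))
}
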