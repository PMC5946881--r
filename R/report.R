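#' Assemble the tiered interpretation report payload
#'
#' Collects every upstream result into one structured payload. The tier
#' partition invariant — the tier row counts must sum to the number of PASS
#' variants — is enforced here as an internal guard.
#'
#' @param sample_id Sample identifier (non-empty).
#' @param variants Tiered, ranked variant table ([rank_within_tiers()]).
#' @param gene_summary Per-gene summary ([aggregate_gene_level()]).
#' @param cna_events CNA gene events ([intersect_genes()]) or NULL.
#' @param cna_segments All input segments (report appendix) or NULL.
#' @param signature_fit A `signature_fit` or NULL (disabled / no SNVs).
#' @param msi_prediction An `msi_prediction` or NULL (disabled).
#' @param tmb_result A `tmb_result`.
#' @param bundle Loaded bundle (manifest feeds the run metadata).
#' @param config Configuration list (snapshotted into metadata).
#' @param n_filtered Count of non-PASS records excluded on input.
#' @return Object of class `tier_report`.
#' @export
build_report <- function(sample_id, variants, gene_summary,
                         cna_events = NULL, cna_segments = NULL,
                         signature_fit = NULL, msi_prediction = NULL,
                         tmb_result = NULL, bundle = NULL,
                         config = default_config(), n_filtered = 0L) {
  stopifnot(is.character(sample_id), nzchar(sample_id))
  tiers <- lapply(1:5, function(t)
    variants[variants$tier == t, , drop = FALSE])
  names(tiers) <- paste0("tier", 1:5)
  if (sum(vapply(tiers, nrow, integer(1))) != nrow(variants))
    stop("internal error: tier partition violated (tier counts do not sum ",
         "to the PASS variant count)", call. = FALSE)
  structure(
    list(schema_version = "1.0",
         sample_id = sample_id,
         metadata = list(
           bundle_version = if (!is.null(bundle))
             bundle$manifest$bundle_version else NA_character_,
           n_pass_variants = nrow(variants),
           n_filtered_records = n_filtered,
           config = config[order(names(config))]),
         tiers = tiers,
         gene_summary = gene_summary,
         cna_events = cna_events,
         cna_segments = cna_segments,
         signature_fit = signature_fit,
         msi_prediction = msi_prediction,
         tmb_result = tmb_result),
    class = "tier_report")
}

#' @export
print.tier_report <- function(x, ...) {
  cat("Tiered somatic interpretation report - sample ", x$sample_id, "\n",
      sep = "")
  cnt <- vapply(x$tiers, nrow, integer(1))
  cat("  variants: ", x$metadata$n_pass_variants, " PASS (",
      x$metadata$n_filtered_records, " filtered) | ",
      paste(sprintf("T%d:%d", 1:5, cnt), collapse = " "), "\n", sep = "")
  if (!is.null(x$tmb_result))
    cat("  TMB: ", format(x$tmb_result$tmb, digits = 4), " mut/Mb\n", sep = "")
  if (!is.null(x$msi_prediction))
    cat("  MSI: ", x$msi_prediction$status, "\n", sep = "")
  if (!is.null(x$signature_fit))
    cat("  signatures: ",
        paste(sprintf("%s=%.2f", names(x$signature_fit$fractions),
                      x$signature_fit$fractions), collapse = ", "),
        "\n", sep = "")
  if (!is.null(x$cna_events))
    cat("  CNA events: ", nrow(x$cna_events), "\n", sep = "")
  invisible(x)
}

# variant table -> list of plain row lists for JSON
variant_rows_payload <- function(v) {
  lapply(seq_len(nrow(v)), function(i) {
    em <- v$evidence_matches[[i]]
    list(
      chrom = v$chrom[i], pos = v$pos[i], ref = v$ref[i], alt = v$alt[i],
      variant_class = v$variant_class[i], gene_symbol = v$gene_symbol[i],
      transcript_id = v$transcript_id[i], consequence = v$consequence[i],
      hgvsp = v$hgvsp[i], hgvsc = v$hgvsc[i], impact = v$impact[i],
      tier = v$tier[i], rank_in_tier = v$rank_in_tier[i],
      rationale = as.list(v$rationale[[i]]),
      hotspot_overlap = v$hotspot_overlap[i],
      hotspot_source = v$hotspot_source[i],
      pathogenicity = list(n_algorithms = v$patho_n_algorithms[i],
                           n_damaging = v$patho_n_damaging[i],
                           label = v$patho_label[i]),
      gene = list(known = v$gene_known[i], is_oncogene = v$is_oncogene[i],
                  is_tsg = v$is_tsg[i], in_census = v$in_census[i],
                  literature_score = v$literature_score[i],
                  drugs = v$gene_drugs[i]),
      evidence_matches = if (is.null(em)) list() else
        lapply(seq_len(nrow(em)), function(j) as.list(em[j, , drop = FALSE])),
      frequencies = if (is.null(v$frequencies[[i]])) list() else
        lapply(seq_len(nrow(v$frequencies[[i]])), function(j)
          as.list(v$frequencies[[i]][j, , drop = FALSE])))
  })
}

df_payload <- function(d) {
  if (is.null(d) || nrow(d) == 0L) return(list())
  lapply(seq_len(nrow(d)), function(i) as.list(d[i, , drop = FALSE]))
}

report_payload <- function(report) {
  sf <- report$signature_fit
  msi <- report$msi_prediction
  tmb <- report$tmb_result
  meta <- report$metadata
  # multi-element vectors become lists so that serialize -> parse ->
  # serialize is byte-stable
  meta$config <- lapply(meta$config, function(x)
    if (length(x) > 1L) as.list(x) else x)
  list(
    schema_version = report$schema_version,
    sample_id = report$sample_id,
    metadata = meta,
    tiers = lapply(report$tiers, variant_rows_payload),
    gene_summary = df_payload(report$gene_summary),
    cna = list(
      events = df_payload(report$cna_events),
      segments = df_payload(report$cna_segments)),
    signatures = if (is.null(sf)) NULL else list(
      fractions = as.list(sf$fractions),
      aetiologies = as.list(sf$aetiologies),
      reconstruction_cosine = sf$reconstruction_cosine,
      n_mutations = sf$n_mutations,
      low_confidence = sf$low_confidence),
    msi = if (is.null(msi)) NULL else list(
      status = msi$status, probability = msi$probability,
      features = msi$features, n_variants = msi$n_variants),
    tmb = if (is.null(tmb)) NULL else list(
      n_counted = tmb$n_counted, target_size_mb = tmb$target_size_mb,
      tmb = tmb$tmb))
}

report_json_string <- function(payload) {
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", pretty = TRUE)
}

# flat TSV view of one tier's variants
tier_tsv_table <- function(v) {
  data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    variant_class = v$variant_class, gene_symbol = v$gene_symbol,
    consequence = v$consequence, hgvsp = v$hgvsp, impact = v$impact,
    tier = v$tier, rank_in_tier = v$rank_in_tier,
    rationale = vapply(v$rationale, paste, character(1), collapse = ";"),
    n_evidence_matches = vapply(v$evidence_matches, function(e)
      if (is.null(e)) 0L else nrow(e), integer(1)),
    hotspot_overlap = v$hotspot_overlap,
    pathogenicity = v$patho_label,
    literature_score = v$literature_score,
    stringsAsFactors = FALSE)
}

#' Render a report to files
#'
#' Writes any subset of three formats into `outdir`:
#' `<sample_id>.report.json` (schema-versioned payload),
#' `<sample_id>.tier1..5.tsv` plus `<sample_id>.cna.tsv`, and
#' `<sample_id>.report.html` (a single self-contained static page with
#' sections in tier order). Rendering is pure: the same payload always
#' produces byte-identical files.
#'
#' @param report A `tier_report`.
#' @param formats Subset of `c("json", "tsv", "html")`.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
render_report <- function(report, formats = c("json", "tsv", "html"), outdir) {
  stopifnot(all(formats %in% c("json", "tsv", "html")))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir,
                                call. = FALSE)
  paths <- character(0)
  base <- file.path(outdir, report$sample_id)
  if ("json" %in% formats) {
    p <- paste0(base, ".report.json")
    writeLines(report_json_string(report_payload(report)), p)
    paths <- c(paths, p)
  }
  if ("tsv" %in% formats) {
    for (t in 1:5) {
      p <- paste0(base, ".tier", t, ".tsv")
      utils::write.table(tier_tsv_table(report$tiers[[t]]), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
    p <- paste0(base, ".cna.tsv")
    cna <- report$cna_events
    if (is.null(cna))
      cna <- data.frame(gene_symbol = character(), chrom = character(),
                        seg_start = integer(), seg_end = integer(),
                        log2_ratio = numeric(), call = character(),
                        overlap_bp = integer(), overlap_fraction = numeric(),
                        literature_score = numeric(),
                        n_gene_evidence = integer(),
                        evidence_ids = character(), stringsAsFactors = FALSE)
    utils::write.table(cna, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("html" %in% formats) {
    p <- paste0(base, ".report.html")
    writeLines(report_html_string(report), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(d) {
  if (is.null(d) || nrow(d) == 0L) return("<p class='empty'>No entries.</p>")
  head <- paste0("<tr>", paste0("<th>", html_escape(names(d)), "</th>",
                                collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(d)), function(i)
    paste0("<tr>", paste0("<td>",
      html_escape(vapply(d[i, , drop = FALSE], function(x)
        format(x[[1]], digits = 6), character(1))), "</td>", collapse = ""),
      "</tr>"), character(1))
  paste0("<table>", head, paste(rows, collapse = ""), "</table>")
}

report_html_string <- function(report) {
  sec <- function(title, body)
    paste0("<section><h2>", html_escape(title), "</h2>", body, "</section>")
  tier_titles <- c(
    "Tier 1 - actionable biomarkers",
    "Tier 2 - hotspots and lower-level evidence",
    "Tier 3 - protein-altering variants in cancer genes",
    "Tier 4 - other protein-altering variants",
    "Tier 5 - synonymous and non-coding variants")
  tier_secs <- vapply(1:5, function(t)
    sec(tier_titles[t], html_table(tier_tsv_table(report$tiers[[t]]))),
    character(1))
  sig <- report$signature_fit
  msi <- report$msi_prediction
  tmb <- report$tmb_result
  sig_sec <- if (is.null(sig)) "" else sec("Mutational signatures",
    html_table(data.frame(
      signature = names(sig$fractions),
      fraction = round(unname(sig$fractions), 4),
      aetiology = unname(sig$aetiologies),
      stringsAsFactors = FALSE)))
  msi_sec <- if (is.null(msi)) "" else sec("Microsatellite instability",
    paste0("<p>Status: <b>", html_escape(msi$status), "</b>",
           if (!is.na(msi$probability))
             paste0(" (P[MSI-high] = ", round(msi$probability, 3), ")"),
           "</p>"))
  tmb_sec <- if (is.null(tmb)) "" else sec("Tumor mutational burden",
    paste0("<p><b>", format(tmb$tmb, digits = 4), "</b> mutations/Mb (",
           tmb$n_counted, " qualifying variants / ", tmb$target_size_mb,
           " Mb)</p>"))
  cna_sec <- sec("Copy-number events", html_table(report$cna_events))
  gene_sec <- sec("Mutated gene summary", html_table(report$gene_summary))
  paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'><title>",
    html_escape(report$sample_id), " - tiered somatic report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:",
    "collapse}td,th{border:1px solid #999;padding:2px 6px;font-size:12px}",
    "h2{border-bottom:2px solid #444}.empty{color:#777}</style></head><body>",
    "<h1>Somatic interpretation report - ", html_escape(report$sample_id),
    "</h1><p>Bundle: ", html_escape(as.character(
      report$metadata$bundle_version)), " | PASS variants: ",
    report$metadata$n_pass_variants, " | excluded records: ",
    report$metadata$n_filtered_records, "</p>",
    paste(tier_secs, collapse = ""),
    cna_sec, sig_sec, msi_sec, tmb_sec, gene_sec,
    "</body></html>")
}
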