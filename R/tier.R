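#' Assign clinical-relevance tiers to annotated variants
#'
#' Every SNV/indel is placed in exactly one of five tiers, from actionable
#' biomarkers down to variants of unknown significance. Rules are evaluated
#' in order and the first match wins:
#' \enumerate{
#'   \item Tier 1 — evidence match at exact-allele or codon granularity with
#'     evidence level A or B (actionable markers);
#'   \item Tier 2 — evidence match at any granularity with level C–E, or
#'     overlap with a known hotspot / predicted driver / curated mutation;
#'   \item Tier 3 — protein-altering consequence (impact HIGH or MODERATE)
#'     in a gene flagged oncogene, tumor suppressor, or cancer-gene-census
#'     member;
#'   \item Tier 4 — any other protein-altering consequence;
#'   \item Tier 5 — synonymous or non-coding consequence.
#' }
#' The levels and granularities gating Tiers 1–2 are configuration keys.
#' The function is total and deterministic; each assignment carries the
#' machine-readable rule codes that fired.
#'
#' @param variants Annotated variant table ([annotate_variants()]).
#' @param config Configuration list.
#' @return The table with added columns `tier` (integer 1–5) and `rationale`
#'   (list-column of rule-code character vectors).
#' @export
assign_tiers <- function(variants, config = default_config()) {
  n <- nrow(variants)
  tier <- integer(n)
  rationale <- vector("list", n)
  for (i in seq_len(n)) {
    em <- variants$evidence_matches[[i]]
    codes <- character(0)
    protein_altering <- variants$impact[i] %in% c("HIGH", "MODERATE")
    flagged <- isTRUE(variants$is_oncogene[i]) || isTRUE(variants$is_tsg[i]) ||
      isTRUE(variants$in_census[i])

    t1 <- !is.null(em) &&
      any(em$evidence_level %in% config$tier1_levels &
          em$granularity %in% config$tier1_granularities)
    t2_ev <- !is.null(em) && any(em$evidence_level %in% config$tier2_levels)
    t2_hs <- isTRUE(variants$hotspot_overlap[i])

    if (t1) {
      tier[i] <- 1L
      codes <- "EVIDENCE_AB_ALLELE_OR_CODON"
    } else if (t2_ev || t2_hs) {
      tier[i] <- 2L
      if (t2_ev) codes <- c(codes, "EVIDENCE_CDE")
      if (t2_hs) codes <- c(codes, paste0("HOTSPOT_",
        toupper(gsub(",", "_", variants$hotspot_source[i]))))
    } else if (protein_altering && flagged) {
      tier[i] <- 3L
      codes <- c("PROTEIN_ALTERING_CANCER_GENE",
                 c("ONCOGENE", "TSG", "CENSUS")[c(
                   isTRUE(variants$is_oncogene[i]),
                   isTRUE(variants$is_tsg[i]),
                   isTRUE(variants$in_census[i]))])
    } else if (protein_altering) {
      tier[i] <- 4L
      codes <- "PROTEIN_ALTERING"
    } else {
      tier[i] <- 5L
      codes <- "SYNONYMOUS_OR_NONCODING"
    }
    rationale[[i]] <- codes
  }
  variants$tier <- tier
  variants$rationale <- rationale
  variants
}

# best (lowest) evidence-level rank and granularity rank among a variant's
# matches; Inf when no matches
best_evidence_rank <- function(em, levels_order = c("A", "B", "C", "D", "E"),
                               gran_order = c("exact_allele", "codon", "gene")) {
  if (is.null(em) || nrow(em) == 0L) return(c(level = Inf, gran = Inf))
  lv <- match(em$evidence_level, levels_order)
  gr <- match(em$granularity, gran_order)
  best <- order(lv, gr)[1]
  c(level = lv[best], gran = gr[best])
}

#' Order tiered variants for reporting
#'
#' Tiers 1–2 are ordered by evidence strength (level A before E, then
#' granularity exact < codon < gene, then gene symbol); Tiers 3–5 are
#' prioritized by descending literature-association score, then gene symbol,
#' then position. The original input index is the final tie-break, making
#' the sort a stable total order that is invariant under input permutation
#' of distinct variants.
#'
#' @param variants Tiered variant table ([assign_tiers()]).
#' @return The same table, re-ordered, with a `rank_in_tier` column.
#' @export
rank_within_tiers <- function(variants) {
  n <- nrow(variants)
  if (n == 0L) {
    variants$rank_in_tier <- integer(0)
    return(variants)
  }
  lv <- numeric(n)
  gr <- numeric(n)
  for (i in seq_len(n)) {
    r <- best_evidence_rank(variants$evidence_matches[[i]])
    lv[i] <- r["level"]
    gr[i] <- r["gran"]
  }
  key1 <- ifelse(variants$tier <= 2L, lv, -variants$literature_score)
  key2 <- ifelse(variants$tier <= 2L, gr, 0)
  ord <- order(variants$tier, key1, key2, variants$gene_symbol,
               variants$chrom, variants$pos, seq_len(n))
  out <- variants[ord, , drop = FALSE]
  out$rank_in_tier <- stats::ave(seq_len(n), out$tier,
                                 FUN = seq_along)
  rownames(out) <- NULL
  out
}
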