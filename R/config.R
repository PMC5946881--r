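#' Default interpretation configuration
#'
#' All tunable thresholds of the engine in one flat list. Every value can be
#' overridden via `...` (unknown keys are rejected).
#'
#' Keys:
#' \describe{
#'   \item{csq_field_name}{INFO field holding the per-transcript consequence
#'     blocks (default `"CSQ"`).}
#'   \item{csq_subfields}{Ordered subfield names of one consequence block.}
#'   \item{retain_nonpass}{Keep records whose FILTER is not PASS/"." (default
#'     `FALSE`; excluded records are counted and surfaced in report metadata).}
#'   \item{tier1_levels, tier1_granularities}{Evidence levels and match
#'     granularities that gate Tier 1.}
#'   \item{tier2_levels}{Evidence levels that place a match in Tier 2.}
#'   \item{patho_min_algorithms, patho_damaging_fraction}{Consensus
#'     pathogenicity rule: label `damaging` iff
#'     n_damaging >= ceiling(fraction * n_algorithms) and
#'     n_algorithms >= minimum.}
#'   \item{sig_prune_threshold}{Signature fractions below this are pruned and
#'     the fit repeated (default 0.06).}
#'   \item{sig_min_mutations}{SNV count under which a signature fit is flagged
#'     low-confidence (default 50).}
#'   \item{msi_min_variants}{Variant count under which the MSI call is
#'     `undetermined` (default 20).}
#'   \item{msi_cutoff}{Probability cutoff mapping the logistic score to
#'     MSI-high (default 0.5).}
#'   \item{tmb_target_size_mb}{Coding territory (Mb) used as the mutational
#'     burden denominator (default 36.0).}
#'   \item{cna_gain_log2, cna_loss_log2}{Segment log2-ratio thresholds for
#'     gain/loss calls (defaults +0.8 / -0.8).}
#'   \item{tumor_type}{Optional tumor type of the query sample; used only to
#'     record tumor-type concordance on evidence matches, never as a filter.}
#' }
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    csq_field_name = "CSQ",
    csq_subfields = c("Allele", "Consequence", "IMPACT", "SYMBOL", "Feature",
                      "HGVSc", "HGVSp", "CANONICAL", "PICK"),
    retain_nonpass = FALSE,
    tier1_levels = c("A", "B"),
    tier1_granularities = c("exact_allele", "codon"),
    tier2_levels = c("C", "D", "E"),
    patho_min_algorithms = 2L,
    patho_damaging_fraction = 2 / 3,
    sig_prune_threshold = 0.06,
    sig_min_mutations = 50L,
    msi_min_variants = 20L,
    msi_cutoff = 0.5,
    tmb_target_size_mb = 36.0,
    cna_gain_log2 = 0.8,
    cna_loss_log2 = -0.8,
    tumor_type = NA_character_
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  cfg
}
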