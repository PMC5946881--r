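#' Parse a protein position out of an HGVS protein string
#'
#' Accepts one- and three-letter amino-acid codes ("p.V600E",
#' "p.Gly12Asp", optionally prefixed by a protein accession) and returns the
#' reference amino acid (one-letter) with its position. Total function:
#' unparseable or empty input yields NULL, never an error.
#'
#' @param hgvsp HGVS protein change string (or "", NA).
#' @return List with `ref_aa` and `position`, or NULL.
#' @export
parse_protein_position <- function(hgvsp) {
  if (is.null(hgvsp) || length(hgvsp) != 1L || is.na(hgvsp) || hgvsp == "")
    return(NULL)
  s <- sub("^.*:", "", hgvsp)               # strip ENSP...: prefix
  m <- regmatches(s, regexec("^p\\.\\(?([A-Za-z]{1,3})([0-9]+)", s))[[1]]
  if (length(m) != 3L) return(NULL)
  aa <- m[2]
  if (nchar(aa) == 3L) {
    aa <- AA_THREE_TO_ONE[tolower(aa)]
    if (is.na(aa)) return(NULL)
  } else if (nchar(aa) != 1L || !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]]) {
    return(NULL)
  }
  list(ref_aa = unname(aa), position = as.integer(m[3]))
}

AA_THREE_TO_ONE <- c(
  ala = "A", arg = "R", asn = "N", asp = "D", cys = "C", gln = "Q",
  glu = "E", gly = "G", his = "H", ile = "I", leu = "L", lys = "K",
  met = "M", phe = "F", pro = "P", ser = "S", thr = "T", trp = "W",
  tyr = "Y", val = "V", ter = "*", sec = "U")

# consensus over per-algorithm pathogenicity calls; labels beyond the pinned
# ones: tolerated iff zero damaging calls, mixed otherwise
consensus_pathogenicity <- function(calls, min_algorithms = 2L,
                                    damaging_fraction = 2 / 3) {
  n <- length(calls)
  n_dam <- sum(calls == "damaging")
  label <- if (n == 0L) "unknown"
    else if (n >= min_algorithms && n_dam >= ceiling(damaging_fraction * n))
      "damaging"
    else if (n_dam == 0L) "tolerated"
    else "mixed"
  list(n_algorithms = n, n_damaging = n_dam, label = label)
}

#' Annotate variants against the knowledge bundle
#'
#' Performs the allele-specific and gene-level joins for every variant:
#' \itemize{
#'   \item evidence matches at three granularities — `exact_allele` (full
#'     normalized allele-key equality), `codon` (gene + protein-position
#'     equality, SNV/MNV only), `gene` (symbol equality for gene-level
#'     items); tumor-type concordance with `tumor_type` is recorded on each
#'     match but never used as a filter;
#'   \item hotspot/driver codon overlap via the parsed HGVSp position
#'     (indels never codon-match; their protein-position semantics are
#'     ambiguous);
#'   \item tumor-type frequencies of the exact allele;
#'   \item consensus pathogenicity over the per-algorithm calls;
#'   \item the gene-level annotation record (a variant whose gene is absent
#'     from the gene table gets an empty annotation and a warning, not an
#'     error).
#' }
#' The operation is pure: bundle row order never changes its output.
#'
#' @param variants Variant table from [read_somatic_vcf()].
#' @param bundle Loaded bundle.
#' @param config Configuration list (see [default_config()]).
#' @return The variant table with added columns: list-columns
#'   `evidence_matches` and `frequencies`, plus `hotspot_overlap`,
#'   `hotspot_source`, `patho_n_algorithms`, `patho_n_damaging`,
#'   `patho_label`, `gene_known`, `is_oncogene`, `is_tsg`, `in_census`,
#'   `literature_score`, `gene_drugs`.
#' @export
annotate_variants <- function(variants, bundle, config = default_config()) {
  n <- nrow(variants)
  ev <- bundle$evidence
  ev_allele <- ev[ev$has_allele, , drop = FALSE]
  ev_gene <- ev[!ev$has_allele, , drop = FALSE]
  ev_codon <- ev[!is.na(ev$protein_position), , drop = FALSE]
  ev_allele_keys <- allele_key(ev_allele$chrom, ev_allele$pos, ev_allele$ref,
                               ev_allele$alt)
  freq_keys <- allele_key(bundle$frequencies$chrom, bundle$frequencies$pos,
                          bundle$frequencies$ref, bundle$frequencies$alt)
  patho_keys <- allele_key(bundle$pathogenicity$chrom, bundle$pathogenicity$pos,
                           bundle$pathogenicity$ref, bundle$pathogenicity$alt)
  keys <- allele_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  genes1 <- bundle$genes[!duplicated(bundle$genes$gene_symbol), , drop = FALSE]
  tt <- config$tumor_type

  evidence_matches <- vector("list", n)
  frequencies <- vector("list", n)
  hotspot_overlap <- logical(n)
  hotspot_source <- character(n)
  patho_n <- integer(n)
  patho_dam <- integer(n)
  patho_label <- character(n)
  gene_known <- logical(n)
  is_onc <- logical(n)
  is_tsg <- logical(n)
  in_census <- logical(n)
  lit <- numeric(n)
  gene_drugs <- character(n)
  unknown_genes <- character(0)

  as_match <- function(rows, granularity) {
    if (nrow(rows) == 0L) return(NULL)
    data.frame(evidence_id = rows$id, granularity = granularity,
               evidence_level = rows$evidence_level,
               evidence_type = rows$evidence_type,
               clinical_significance = rows$clinical_significance,
               tumor_type = rows$tumor_type,
               tumor_type_concordant = !is.na(tt) &
                 (rows$tumor_type == tt | rows$tumor_type == "any"),
               drug = rows$drug, citation = rows$citation,
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(n)) {
    gene <- variants$gene_symbol[i]
    pp <- parse_protein_position(variants$hgvsp[i])
    is_indel <- variants$variant_class[i] %in% c("insertion", "deletion")

    m_exact <- as_match(ev_allele[ev_allele_keys == keys[i], , drop = FALSE],
                        "exact_allele")
    m_codon <- NULL
    if (!is.null(pp) && !is_indel && nzchar(gene)) {
      cand <- ev_codon[ev_codon$gene_symbol == gene &
                       ev_codon$protein_position == pp$position, , drop = FALSE]
      # exclude items already matched at exact-allele granularity
      if (!is.null(m_exact))
        cand <- cand[!cand$id %in% m_exact$evidence_id, , drop = FALSE]
      m_codon <- as_match(cand, "codon")
    }
    m_gene <- if (nzchar(gene))
      as_match(ev_gene[ev_gene$gene_symbol == gene, , drop = FALSE], "gene")
    else NULL
    em <- rbind(m_exact, m_codon, m_gene)
    if (!is.null(em)) em <- em[order(em$evidence_id), , drop = FALSE]
    evidence_matches[i] <- list(em)  # [[<- would drop the element on NULL

    if (!is.null(pp) && !is_indel && nzchar(gene)) {
      hs <- bundle$hotspots[bundle$hotspots$gene_symbol == gene &
                            bundle$hotspots$protein_position == pp$position, ,
                            drop = FALSE]
      hs <- hs[hs$ref_aa == pp$ref_aa | hs$ref_aa %in% c(".", ""), ,
               drop = FALSE]
      if (nrow(hs)) {
        hotspot_overlap[i] <- TRUE
        hotspot_source[i] <- paste(sort(unique(hs$source)), collapse = ",")
      }
    }

    fr <- bundle$frequencies[freq_keys == keys[i], , drop = FALSE]
    frequencies[i] <- list(if (nrow(fr))
      fr[order(fr$tumor_type), c("tumor_type", "count", "cohort_size")]
    else NULL)

    pt <- bundle$pathogenicity[patho_keys == keys[i], , drop = FALSE]
    cp <- consensus_pathogenicity(pt$call, config$patho_min_algorithms,
                                  config$patho_damaging_fraction)
    patho_n[i] <- cp$n_algorithms
    patho_dam[i] <- cp$n_damaging
    patho_label[i] <- cp$label

    g <- match(gene, genes1$gene_symbol)
    if (!is.na(g)) {
      gene_known[i] <- TRUE
      is_onc[i] <- genes1$is_oncogene[g]
      is_tsg[i] <- genes1$is_tsg[g]
      in_census[i] <- genes1$in_cancer_gene_census[g]
      lit[i] <- genes1$literature_score[g]
      gene_drugs[i] <- if (genes1$drugs[g] == ".") "" else genes1$drugs[g]
    } else if (nzchar(gene)) {
      unknown_genes <- c(unknown_genes, gene)
    }
  }
  if (length(unknown_genes))
    warning("gene symbol(s) absent from the bundle gene table: ",
            paste(sort(unique(unknown_genes)), collapse = ", "),
            "; annotated with empty gene records", call. = FALSE)

  variants$evidence_matches <- evidence_matches
  variants$frequencies <- frequencies
  variants$hotspot_overlap <- hotspot_overlap
  variants$hotspot_source <- hotspot_source
  variants$patho_n_algorithms <- patho_n
  variants$patho_n_damaging <- patho_dam
  variants$patho_label <- patho_label
  variants$gene_known <- gene_known
  variants$is_oncogene <- is_onc
  variants$is_tsg <- is_tsg
  variants$in_census <- in_census
  variants$literature_score <- lit
  variants$gene_drugs <- gene_drugs
  variants
}

#' Aggregate annotated variants to a per-gene summary
#'
#' One row per gene with at least one variant, carrying the oncology flags,
#' literature-association score and drug targets, sorted by descending
#' literature score with ties broken by gene symbol.
#'
#' @param variants Annotated variant table ([annotate_variants()]).
#' @return data.frame with columns `gene_symbol`, `n_variants`,
#'   `is_oncogene`, `is_tsg`, `in_census`, `literature_score`, `drugs`.
#' @export
aggregate_gene_level <- function(variants) {
  v <- variants[nzchar(variants$gene_symbol), , drop = FALSE]
  if (nrow(v) == 0L)
    return(data.frame(gene_symbol = character(), n_variants = integer(),
                      is_oncogene = logical(), is_tsg = logical(),
                      in_census = logical(), literature_score = numeric(),
                      drugs = character(), stringsAsFactors = FALSE))
  idx <- split(seq_len(nrow(v)), v$gene_symbol)
  out <- do.call(rbind, lapply(idx, function(ii) {
    data.frame(gene_symbol = v$gene_symbol[ii[1]],
               n_variants = length(ii),
               is_oncogene = v$is_oncogene[ii[1]],
               is_tsg = v$is_tsg[ii[1]],
               in_census = v$in_census[ii[1]],
               literature_score = v$literature_score[ii[1]],
               drugs = v$gene_drugs[ii[1]],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$literature_score, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
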