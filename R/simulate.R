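#' Simulate a somatic tumor VCF against a bundle
#'
#' Draws a synthetic tumor mutation set that is consistent with the bundle's
#' genome (every ref allele matches the reference base) and writes it as an
#' annotated VCF with one picked consequence block per record. The mix is
#' controlled by:
#' \itemize{
#'   \item `evidence_fraction` — fraction of variants placed exactly on
#'     allele-level evidence keys from the bundle (closure with the
#'     annotation joins);
#'   \item `hotspot_fraction` — fraction given an HGVSp string matching a
#'     bundle hotspot codon of their gene;
#'   \item `indel_fraction` — fraction emitted as 1-bp insertions/deletions;
#'   \item `signature_weights` — optional mixing weights over the bundle's
#'     signatures; SNV trinucleotide contexts are then sampled from the
#'     mixture and placed at genome positions carrying that context.
#' }
#' Remaining variants are uniform SNVs inside (mostly) gene spans with
#' consequence terms drawn over missense/synonymous/stop/splice/intron.
#'
#' @param bundle A loaded bundle ([load_bundle()]).
#' @param path Output VCF path.
#' @param seed Integer seed.
#' @param n_variants Number of PASS variants.
#' @param evidence_fraction,hotspot_fraction,indel_fraction Mix fractions.
#' @param signature_weights Named or positional weights over the bundle's
#'   signature columns (normalized internally), or NULL for uniform SNVs.
#' @param disjoint_from_bundle If TRUE, no emitted allele key coincides with
#'   any bundle evidence allele (for join-soundness tests); forces
#'   `evidence_fraction = 0`.
#' @param n_fail Additional records written with `FILTER=LowQual`.
#' @return Invisibly, the variant table that was written (PASS rows only).
#' @export
simulate_somatic_vcf <- function(bundle, path, seed, n_variants = 200L,
                                 evidence_fraction = 0.2,
                                 hotspot_fraction = 0.1,
                                 indel_fraction = 0.05,
                                 signature_weights = NULL,
                                 disjoint_from_bundle = FALSE,
                                 n_fail = 0L) {
  genes <- bundle$genes
  chrom <- names(bundle$genome)[1]
  seqstr <- as.character(bundle$genome[[chrom]])
  L <- nchar(seqstr)
  chars <- strsplit(seqstr, "")[[1]]
  bases <- c("A", "C", "G", "T")
  ev_alleles <- bundle$evidence[bundle$evidence$has_allele, , drop = FALSE]
  ev_keys <- allele_key(ev_alleles$chrom, ev_alleles$pos, ev_alleles$ref,
                        ev_alleles$alt)
  if (disjoint_from_bundle) evidence_fraction <- 0
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

  ctx_index <- NULL
  if (!is.null(signature_weights)) {
    trip <- paste0(chars[1:(L - 2L)], chars[2:(L - 1L)], chars[3:L])
    ctx_index <- split(seq(2L, L - 1L), trip)  # center position by triplet
  }

  gene_at <- function(pos) {
    hit <- which(genes$span_start <= pos & genes$span_end >= pos)
    if (length(hit)) hit[1] else NA_integer_
  }

  cons_pool <- data.frame(
    term = c("missense_variant", "synonymous_variant", "stop_gained",
             "splice_donor_variant", "intron_variant"),
    impact = c("MODERATE", "LOW", "HIGH", "HIGH", "MODIFIER"),
    prob = c(0.5, 0.2, 0.08, 0.07, 0.15), stringsAsFactors = FALSE)

  res <- withr::with_seed(seed, {
    n_ev <- round(n_variants * evidence_fraction)
    if (nrow(ev_alleles) == 0L) n_ev <- 0L
    n_hot <- round(n_variants * hotspot_fraction)
    if (nrow(bundle$hotspots) == 0L) n_hot <- 0L
    rows <- vector("list", n_variants + n_fail)

    make_row <- function(kind) {
      if (kind == "evidence") {
        e <- ev_alleles[sample.int(nrow(ev_alleles), 1L), ]
        hp <- if (!is.na(e$protein_position))
          paste0("p.", e$ref_aa, e$protein_position, sample(aas, 1L)) else ""
        return(data.frame(
          chrom = e$chrom, pos = e$pos, ref = e$ref, alt = e$alt,
          variant_class = variant_class_of(e$ref, e$alt),
          gene_symbol = e$gene_symbol,
          transcript_id = paste0("TX_", e$gene_symbol),
          consequence = "missense_variant", hgvsp = hp, hgvsc = "",
          impact = "MODERATE", stringsAsFactors = FALSE))
      }
      if (kind == "hotspot") {
        h <- bundle$hotspots[sample.int(nrow(bundle$hotspots), 1L), ]
        g <- match(h$gene_symbol, genes$gene_symbol)
        pos <- sample(seq(genes$span_start[g] + 1L, genes$span_end[g] - 1L), 1L)
        ref <- chars[pos]
        alt <- sample(setdiff(bases, ref), 1L)
        return(data.frame(
          chrom = chrom, pos = pos, ref = ref, alt = alt,
          variant_class = "SNV", gene_symbol = h$gene_symbol,
          transcript_id = paste0("TX_", h$gene_symbol),
          consequence = "missense_variant",
          hgvsp = paste0("p.", h$ref_aa, h$protein_position, sample(aas, 1L)),
          hgvsc = "", impact = "MODERATE", stringsAsFactors = FALSE))
      }
      if (kind == "indel") {
        pos <- sample.int(L - 2L, 1L) + 1L
        ref <- chars[pos]
        if (stats::runif(1) < 0.5) {
          alt <- paste0(ref, sample(bases, 1L))
        } else {
          ref <- paste0(chars[pos], chars[pos + 1L])
          alt <- chars[pos]
        }
        g <- gene_at(pos)
        return(data.frame(
          chrom = chrom, pos = pos, ref = ref, alt = alt,
          variant_class = variant_class_of(ref, alt),
          gene_symbol = if (is.na(g)) "" else genes$gene_symbol[g],
          transcript_id = if (is.na(g)) "" else paste0("TX_", genes$gene_symbol[g]),
          consequence = "frameshift_variant", hgvsp = "", hgvsc = "",
          impact = "HIGH", stringsAsFactors = FALSE))
      }
      # plain SNV, context-directed when signature weights given
      if (!is.null(ctx_index)) {
        w <- rep_len(as.numeric(signature_weights),
                     ncol(bundle$signatures$matrix))
        p <- as.numeric(bundle$signatures$matrix %*% (w / sum(w)))
        cls <- sample(mutation_context_classes(), 1L, prob = p)
        five <- substr(cls, 1L, 1L); ref_p <- substr(cls, 3L, 3L)
        alt_p <- substr(cls, 5L, 5L); three <- substr(cls, 7L, 7L)
        fwd <- paste0(five, ref_p, three)
        rev <- paste0(COMPLEMENT[[three]], COMPLEMENT[[ref_p]], COMPLEMENT[[five]])
        cand <- c(ctx_index[[fwd]], ctx_index[[rev]])
        pos <- cand[sample.int(length(cand), 1L)]
        ref <- chars[pos]
        alt <- if (ref == ref_p) alt_p else COMPLEMENT[[alt_p]]
      } else {
        pos <- sample.int(L - 2L, 1L) + 1L
        ref <- chars[pos]
        alt <- sample(setdiff(bases, ref), 1L)
      }
      g <- gene_at(pos)
      ci <- sample.int(nrow(cons_pool), 1L, prob = cons_pool$prob)
      if (is.na(g)) {
        return(data.frame(
          chrom = chrom, pos = pos, ref = ref, alt = alt,
          variant_class = "SNV", gene_symbol = "", transcript_id = "",
          consequence = "intergenic_variant", hgvsp = "", hgvsc = "",
          impact = "MODIFIER", stringsAsFactors = FALSE))
      }
      hp <- if (cons_pool$term[ci] == "missense_variant")
        paste0("p.", sample(aas, 1L), sample.int(900L, 1L), sample(aas, 1L))
      else ""
      data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt, variant_class = "SNV",
        gene_symbol = genes$gene_symbol[g],
        transcript_id = paste0("TX_", genes$gene_symbol[g]),
        consequence = cons_pool$term[ci], hgvsp = hp, hgvsc = "",
        impact = cons_pool$impact[ci], stringsAsFactors = FALSE)
    }

    kinds <- c(rep("evidence", n_ev), rep("hotspot", n_hot),
               rep("indel", round(n_variants * indel_fraction)))
    kinds <- c(kinds, rep("snv", max(0L, n_variants - length(kinds))))
    kinds <- kinds[seq_len(n_variants)]
    for (i in seq_len(n_variants)) {
      row <- make_row(kinds[i])
      if (disjoint_from_bundle) {
        while (allele_key(row$chrom, row$pos, row$ref, row$alt) %in% ev_keys)
          row <- make_row(kinds[i])
      }
      rows[[i]] <- row
    }
    for (i in seq_len(n_fail)) rows[[n_variants + i]] <- make_row("snv")
    all <- do.call(rbind, rows)
    filters <- c(rep("PASS", n_variants), rep("LowQual", n_fail))
    ord <- order(all$chrom, all$pos, all$ref, all$alt)
    write_somatic_vcf(all[ord, ], path, filters = filters[ord])
    all[ord, ][filters[ord] == "PASS", ]
  })
  invisible(res)
}

#' Simulate a copy-number segment file against a bundle genome
#'
#' Writes random non-degenerate segments with log2 ratios drawn from a
#' three-component mixture (gains near +1.5, losses near -1.5, neutral near
#' 0).
#'
#' @param bundle A loaded bundle.
#' @param path Output TSV path.
#' @param seed Integer seed.
#' @param n_segments Number of segments.
#' @return Invisibly, the segment data.frame that was written.
#' @export
simulate_cna_file <- function(bundle, path, seed, n_segments = 12L) {
  chrom <- names(bundle$genome)[1]
  L <- length(bundle$genome[[chrom]])
  withr::with_seed(seed, {
    start <- sort(sample.int(L - 100L, n_segments))
    len <- sample(500:max(1000L, L %/% 10L), n_segments, replace = TRUE)
    end <- pmin(L, start + len)
    grp <- sample(1:3, n_segments, replace = TRUE, prob = c(0.3, 0.2, 0.5))
    log2r <- round(c(stats::rnorm(n_segments, 1.5, 0.3),
                     stats::rnorm(n_segments, -1.5, 0.3),
                     stats::rnorm(n_segments, 0, 0.1))[
                       (grp - 1L) * n_segments + seq_len(n_segments)], 4)
    seg <- data.frame(Chromosome = chrom, Start = start, End = end,
                      Segment_Mean = log2r, stringsAsFactors = FALSE)
    utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(seg)
  })
}

#' Simulate an MSI training cohort of whole-profile features
#'
#' Class-conditional feature distributions: MSI-high tumors have indel
#' fraction ~ Normal(0.25, 0.05) and total mutation rates around 30/Mb; MSS
#' tumors have indel fraction ~ Normal(0.04, 0.02) and rates around 5/Mb.
#' Draws are truncated to valid ranges.
#'
#' @param n_msi,n_mss Class sizes.
#' @param seed Integer seed.
#' @return data.frame with columns `indel_fraction`, `indels_per_mb`,
#'   `snvs_per_mb`, `label` ("MSI-high"/"MSS").
#' @export
simulate_msi_cohort <- function(n_msi, n_mss, seed) {
  withr::with_seed(seed, {
    ifr <- c(pmin(0.9, pmax(0.001, stats::rnorm(n_msi, 0.25, 0.05))),
             pmin(0.9, pmax(0.001, stats::rnorm(n_mss, 0.04, 0.02))))
    tot <- c(pmax(2, stats::rnorm(n_msi, 30, 8)),
             pmax(0.5, stats::rnorm(n_mss, 5, 2)))
    data.frame(indel_fraction = ifr,
               indels_per_mb = tot * ifr,
               snvs_per_mb = tot * (1 - ifr),
               label = rep(c("MSI-high", "MSS"), c(n_msi, n_mss)),
               stringsAsFactors = FALSE)
  })
}
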