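#' The 96 trinucleotide substitution classes in canonical order
#'
#' Single-base substitutions are classified by the substituted pyrimidine
#' (C or T) and its 5' and 3' flanking bases: 6 substitutions x 16 flank
#' pairs. Order is substitution-major (C>A, C>G, C>T, T>A, T>C, T>G) with
#' flanks in lexicographic minor order, e.g. `A[C>A]A`, `A[C>A]C`, ...
#'
#' @return Character vector of length 96.
#' @export
mutation_context_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(p5) paste0(p5, "[", s, "]", bases)))))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# collapse a substitution with flanks to its pyrimidine-centric class string;
# NA when any base is not ACGT
collapse_context <- function(ref, alt, five, three) {
  if (!all(c(ref, alt, five, three) %in% names(COMPLEMENT))) return(NA_character_)
  if (ref %in% c("G", "A")) {
    new5 <- COMPLEMENT[[three]]
    new3 <- COMPLEMENT[[five]]
    ref2 <- COMPLEMENT[[ref]]
    alt2 <- COMPLEMENT[[alt]]
    paste0(new5, "[", ref2, ">", alt2, "]", new3)
  } else {
    paste0(five, "[", ref, ">", alt, "]", three)
  }
}

#' Build the 96-context mutational catalog of a variant set
#'
#' Counts SNVs by trinucleotide substitution class, reading the flanking
#' bases from the genome and reverse-complementing purine-reference
#' substitutions onto the pyrimidine strand. Non-SNVs are ignored; SNVs at a
#' sequence edge (no flank available) are skipped and counted in `n_skipped`.
#' A mismatch between a variant's ref allele and the genome base at its
#' position is a data-integrity error.
#'
#' @param variants Variant table (see [read_somatic_vcf()]).
#' @param genome A [Biostrings::DNAStringSet] whose names are chromosome
#'   names covering all variant positions.
#' @return An object of class `mutational_catalog`: list with `counts`
#'   (named integer vector of length 96), `n_snvs_used`, `n_skipped`,
#'   `n_non_snv`.
#' @export
build_catalog <- function(variants, genome) {
  classes <- mutation_context_classes()
  counts <- stats::setNames(integer(96L), classes)
  snv <- variants[variants$variant_class == "SNV", , drop = FALSE]
  n_skipped <- 0L
  chrom_cache <- list()
  for (i in seq_len(nrow(snv))) {
    chrom <- snv$chrom[i]
    if (is.null(chrom_cache[[chrom]])) {
      if (!chrom %in% names(genome))
        stop("variant ", chrom, ":", snv$pos[i],
             " lies on a chromosome absent from the genome", call. = FALSE)
      chrom_cache[[chrom]] <- as.character(genome[[chrom]])
    }
    seq <- chrom_cache[[chrom]]
    pos <- snv$pos[i]
    if (pos < 1L || pos > nchar(seq))
      stop("variant ", chrom, ":", pos, " is outside the genome sequence",
           call. = FALSE)
    gref <- substr(seq, pos, pos)
    if (gref != snv$ref[i])
      stop("reference mismatch at ", chrom, ":", pos, " (variant ref '",
           snv$ref[i], "', genome '", gref, "')", call. = FALSE)
    if (pos == 1L || pos == nchar(seq)) {
      n_skipped <- n_skipped + 1L
      next
    }
    cls <- collapse_context(snv$ref[i], snv$alt[i],
                            substr(seq, pos - 1L, pos - 1L),
                            substr(seq, pos + 1L, pos + 1L))
    if (is.na(cls)) {
      n_skipped <- n_skipped + 1L
      next
    }
    counts[[cls]] <- counts[[cls]] + 1L
  }
  structure(
    list(counts = counts,
         n_snvs_used = sum(counts),
         n_skipped = n_skipped,
         n_non_snv = nrow(variants) - nrow(snv)),
    class = "mutational_catalog"
  )
}

#' @export
print.mutational_catalog <- function(x, ...) {
  cat("Mutational catalog: ", x$n_snvs_used, " SNVs over 96 contexts (",
      x$n_skipped, " skipped, ", x$n_non_snv, " non-SNV)\n", sep = "")
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  if (length(top)) {
    cat("Top contexts:\n")
    print(utils::head(top, 5L))
  }
  invisible(x)
}
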