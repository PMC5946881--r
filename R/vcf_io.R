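#' Read a somatic VCF into the internal variant table
#'
#' Reads a single-sample (or sample-free) VCF whose INFO field carries
#' VEP-style per-transcript consequence blocks, splits multi-allelic records,
#' normalizes every (pos, ref, alt) with [normalize_allele()], and parses the
#' single "picked" consequence block per variant. Records whose FILTER is
#' neither `PASS` nor `.` are excluded (unless `retain_nonpass`); the count of
#' excluded records is kept in the `n_filtered` attribute for report metadata.
#'
#' Block-to-allele assignment for multi-allelic records uses the `Allele`
#' subfield when present (matched against the raw ALT, its VEP-trimmed form,
#' or `-`); with a single ALT all blocks belong to it. The picked block is the
#' one whose `PICK` subfield is `1`; if the dialect lacks a PICK subfield the
#' fallback ranking is highest impact, then `CANONICAL == "YES"`, then the
#' lexicographically smallest transcript id. More than one picked block for
#' one variant is a hard error.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param csq_subfields Ordered subfield names of one consequence block; must
#'   describe the dialect of the file.
#' @param csq_field Name of the INFO field holding the blocks (default "CSQ").
#' @param retain_nonpass Keep non-PASS records (default FALSE).
#' @return A data.frame with one row per (record, ALT) pair and columns
#'   `chrom`, `pos`, `ref`, `alt`, `variant_class`, `gene_symbol`,
#'   `transcript_id`, `consequence`, `hgvsp`, `hgvsc`, `impact`, plus
#'   attributes `n_filtered` and `n_records`.
#' @export
read_somatic_vcf <- function(path,
                             csq_subfields = default_config()$csq_subfields,
                             csq_field = "CSQ",
                             retain_nonpass = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcf@gt
  if (!is.null(gt) && ncol(gt) > 2L)
    stop("VCF has ", ncol(gt) - 1L,
         " sample columns; this engine accepts single-sample input", call. = FALSE)
  fix <- vcf@fix
  empty <- empty_variant_table()
  if (is.null(fix) || nrow(fix) == 0L) {
    attr(empty, "n_filtered") <- 0L
    attr(empty, "n_records") <- 0L
    return(empty)
  }

  filt <- fix[, "FILTER"]
  pass <- is.na(filt) | filt %in% c("PASS", ".")
  n_filtered <- sum(!pass)
  if (!retain_nonpass) fix <- fix[pass, , drop = FALSE]
  if (nrow(fix) == 0L) {
    attr(empty, "n_filtered") <- n_filtered
    attr(empty, "n_records") <- 0L
    return(empty)
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    rec_id <- paste0(fix[i, "CHROM"], ":", fix[i, "POS"])
    info <- fix[i, "INFO"]
    csq_raw <- extract_info_field(info, csq_field)
    if (is.na(csq_raw))
      stop("record ", rec_id, " has no ", csq_field, " INFO field", call. = FALSE)
    blocks <- parse_csq_blocks(csq_raw, csq_subfields)
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ref <- fix[i, "REF"]
    pos <- as.integer(fix[i, "POS"])
    chrom <- normalize_chrom(fix[i, "CHROM"])
    rows[[i]] <- do.call(rbind, lapply(alts, function(a) {
      blk <- blocks_for_alt(blocks, a, length(alts) > 1L)
      picked <- pick_block(blk, rec_id)
      nm <- normalize_allele(pos, ref, a)
      data.frame(
        chrom = chrom, pos = nm$pos, ref = nm$ref, alt = nm$alt,
        variant_class = variant_class_of(nm$ref, nm$alt),
        gene_symbol = picked$SYMBOL %||% "",
        transcript_id = picked$Feature %||% "",
        consequence = picked$Consequence %||% "",
        hgvsp = picked$HGVSp %||% "",
        hgvsc = picked$HGVSc %||% "",
        impact = picked$IMPACT %||% "MODIFIER",
        stringsAsFactors = FALSE
      )
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_filtered") <- n_filtered
  attr(out, "n_records") <- nrow(fix)
  out
}

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), variant_class = character(),
             gene_symbol = character(), transcript_id = character(),
             consequence = character(), hgvsp = character(),
             hgvsc = character(), impact = character(),
             stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) {
  if (is.null(x) || length(x) == 0L || is.na(x[[1]])) y else x
}

# pull one INFO field value; NA if absent, "" for flag-style presence
extract_info_field <- function(info, field) {
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  hit <- grep(paste0("^", field, "(=|$)"), parts, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(paste0("^", field, "=?"), "", hit[[1]])
}

# one data.frame row per transcript block, columns = csq_subfields
parse_csq_blocks <- function(csq_raw, csq_subfields) {
  blocks <- strsplit(csq_raw, ",", fixed = TRUE)[[1]]
  vals <- lapply(blocks, function(b) {
    f <- strsplit(b, "|", fixed = TRUE)[[1]]
    length(f) <- length(csq_subfields)  # pad trailing empties
    f[is.na(f)] <- ""
    f
  })
  out <- as.data.frame(do.call(rbind, vals), stringsAsFactors = FALSE)
  names(out) <- csq_subfields
  out
}

blocks_for_alt <- function(blocks, alt, multi) {
  if (!multi || !("Allele" %in% names(blocks))) return(blocks)
  vep_alt <- if (nchar(alt) > 1L) substring(alt, 2L) else alt
  keep <- blocks$Allele %in% c(alt, vep_alt, "-")
  if (!any(keep)) blocks else blocks[keep, , drop = FALSE]
}

impact_rank <- function(impact) {
  match(impact, c("HIGH", "MODERATE", "LOW", "MODIFIER"), nomatch = 5L)
}

# select the single picked block; deterministic fallback when PICK is absent
pick_block <- function(blocks, rec_id) {
  if ("PICK" %in% names(blocks)) {
    hit <- which(blocks$PICK == "1")
    if (length(hit) > 1L)
      stop("record ", rec_id, " has ", length(hit),
           " consequence blocks flagged as picked; expected exactly one",
           call. = FALSE)
    if (length(hit) == 1L) return(as.list(blocks[hit, , drop = FALSE]))
  }
  canon <- if ("CANONICAL" %in% names(blocks)) blocks$CANONICAL == "YES" else
    rep(FALSE, nrow(blocks))
  tx <- if ("Feature" %in% names(blocks)) blocks$Feature else
    as.character(seq_len(nrow(blocks)))
  ord <- order(impact_rank(blocks$IMPACT %||% "MODIFIER"), !canon, tx)
  as.list(blocks[ord[1L], , drop = FALSE])
}

#' Write a variant table as a minimal annotated VCF
#'
#' Emits normalized variants as VCF 4.2 with a single consequence block per
#' record (the picked block), used for fixture generation and round-trip
#' checks.
#'
#' @param variants Variant table as returned by [read_somatic_vcf()].
#' @param path Output path.
#' @param filters Optional per-row FILTER values (default all `PASS`).
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(variants, path, filters = NULL) {
  if (is.null(filters)) filters <- rep("PASS", nrow(variants))
  sub <- default_config()$csq_subfields
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: ", paste(sub, collapse = "|"), "\">"),
    paste0("##contig=<ID=", unique(variants$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  body <- if (nrow(variants)) {
    csq <- paste(variants$alt, variants$consequence, variants$impact,
                 variants$gene_symbol, variants$transcript_id,
                 variants$hgvsc, variants$hgvsp, "", "1", sep = "|")
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt, ".",
          filters, paste0("CSQ=", csq), sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a copy-number segment file
#'
#' Reads a TSV with header columns Chromosome, Start, End, Segment_Mean
#' (matched case-insensitively). Coordinates are taken as 1-based inclusive;
#' chromosome names are normalized by stripping a leading "chr".
#'
#' @param path Path to the tab-separated segment file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `log2_ratio`,
#'   rows in file order.
#' @export
read_cna_segments <- function(path) {
  if (!file.exists(path)) stop("CNA segment file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  want <- c("chromosome", "start", "end", "segment_mean")
  idx <- match(want, tolower(names(raw)))
  if (anyNA(idx))
    stop("CNA file is missing required column(s): ",
         paste(c("Chromosome", "Start", "End", "Segment_Mean")[is.na(idx)],
               collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      log2_ratio = numeric(), stringsAsFactors = FALSE))
  num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric ", col, " value '", x[bad[1]], "' at data line ",
           bad[1], " of ", path, call. = FALSE)
    v
  }
  out <- data.frame(
    chrom = normalize_chrom(raw[[idx[1]]]),
    start = as.integer(num(raw[[idx[2]]], "Start")),
    end = as.integer(num(raw[[idx[3]]], "End")),
    log2_ratio = num(raw[[idx[4]]], "Segment_Mean"),
    stringsAsFactors = FALSE
  )
  bad <- which(out$start > out$end)
  if (length(bad))
    stop("segment start > end at data line ", bad[1], " of ", path, call. = FALSE)
  out
}
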