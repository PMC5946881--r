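#' Normalize a variant allele to its minimal anchored form
#'
#' Trims bases shared between the reference and alternate allele so that a
#' variant has a single canonical representation, which is what makes exact
#' allele joins against knowledge-bundle records possible. The shared suffix
#' is trimmed first, then the shared prefix; for indels at least one base is
#' always retained on each side (the VCF-style anchor base), which keeps the
#' representation left-aligned among minimal forms. The position is advanced
#' by the number of prefix bases removed. The operation is idempotent.
#'
#' @param pos 1-based position of the first reference base (integer scalar).
#' @param ref Reference allele, non-empty string over ACGT.
#' @param alt Alternate allele, non-empty string over ACGT.
#' @return A list with elements `pos`, `ref`, `alt` in normalized form.
#' @examples
#' normalize_allele(100, "TC", "TG")    # list(pos = 101, ref = "C", alt = "G")
#' normalize_allele(100, "ATTT", "ATT") # list(pos = 100, ref = "AT", alt = "A")
#' @export
normalize_allele <- function(pos, ref, alt) {
  stopifnot(length(pos) == 1L, length(ref) == 1L, length(alt) == 1L)
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (!grepl("^[ACGT]+$", ref))
    stop("ref allele '", ref, "' contains non-ACGT characters", call. = FALSE)
  if (!grepl("^[ACGT]+$", alt))
    stop("alt allele '", alt, "' contains non-ACGT characters", call. = FALSE)
  if (identical(ref, alt))
    stop("ref and alt alleles are identical ('", ref, "')", call. = FALSE)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be a positive integer", call. = FALSE)

  # shared suffix first, keeping >= 1 base on each side
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # then shared prefix, advancing pos
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Derive the variant class from normalized alleles
#'
#' @param ref,alt Normalized alleles (character vectors, recycled).
#' @return Character vector over `"SNV"`, `"MNV"`, `"insertion"`, `"deletion"`.
#' @export
variant_class_of <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  out <- character(length(nr))
  out[nr == 1L & na == 1L] <- "SNV"
  out[nr > 1L & nr == na] <- "MNV"
  out[nr > na] <- "deletion"
  out[nr < na] <- "insertion"
  out
}

# canonical "chrom:pos:ref:alt" key used by every exact-allele join
allele_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# strip an optional leading "chr"/"Chr" prefix from chromosome names
normalize_chrom <- function(chrom) {
  sub("^[Cc]hr", "", as.character(chrom))
}
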