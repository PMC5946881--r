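#' Estimate mutational-signature contributions by non-negative least squares
#'
#' Decomposes a 96-context mutational catalog over a reference signature
#' matrix. The normalized catalog is fit by NNLS against all signature
#' columns; signatures contributing less than `prune_threshold` of the
#' activity are removed and the fit repeated on the survivors until stable
#' (sparse refits avoid spreading noise over many near-zero signatures).
#' Surviving fractions are renormalized to sum to 1. The reconstruction
#' cosine (cosine similarity between the normalized catalog and its fitted
#' reconstruction) reports how well the retained signatures explain the
#' profile. Fits on fewer than `min_mutations` SNVs are returned but flagged
#' low-confidence.
#'
#' @param catalog A `mutational_catalog` (see [build_catalog()]) or a named
#'   96-vector of counts in canonical context order.
#' @param signatures A `signature_matrix` (from a bundle) or a 96 x k
#'   non-negative matrix with columns summing to 1.
#' @param prune_threshold Minimum retained fraction (default 0.06).
#' @param min_mutations SNV count below which the fit is flagged
#'   low-confidence (default 50).
#' @return Object of class `signature_fit`: `fractions` (named, sum 1),
#'   `reconstruction_cosine`, `n_mutations`, `low_confidence`, `aetiologies`.
#' @export
fit_signatures <- function(catalog, signatures, prune_threshold = 0.06,
                           min_mutations = 50L) {
  counts <- if (inherits(catalog, "mutational_catalog")) catalog$counts
            else catalog
  W <- if (inherits(signatures, "signature_matrix")) signatures$matrix
       else signatures
  aet <- if (inherits(signatures, "signature_matrix")) signatures$aetiologies
         else stats::setNames(rep("unknown", ncol(W)), colnames(W))
  stopifnot(length(counts) == 96L, nrow(W) == 96L)
  n <- sum(counts)
  if (n == 0L) stop("no SNVs for signature analysis", call. = FALSE)
  y <- as.numeric(counts) / n

  active <- seq_len(ncol(W))
  repeat {
    coef <- pracma::lsqnonneg(W[, active, drop = FALSE], y)$x
    if (sum(coef) == 0) {  # degenerate: fall back to best single signature
      rss <- apply(W[, active, drop = FALSE], 2, function(w)
        sum((y - w * sum(y * w) / sum(w * w))^2))
      active <- active[which.min(rss)]
      coef <- sum(y * W[, active]) / sum(W[, active]^2)
      break
    }
    frac <- coef / sum(coef)
    drop <- frac < prune_threshold
    if (!any(drop) || all(drop)) {
      if (all(drop)) {  # keep the dominant signature rather than none
        keep <- which.max(frac)
        if (length(active) > 1L) {
          active <- active[keep]
          next
        }
      }
      break
    }
    active <- active[!drop]
  }
  recon <- as.numeric(W[, active, drop = FALSE] %*% coef)
  cosine <- sum(y * recon) / sqrt(sum(y^2) * sum(recon^2))
  fractions <- stats::setNames(coef / sum(coef), colnames(W)[active])
  structure(
    list(fractions = fractions,
         reconstruction_cosine = cosine,
         residual = sum((y - recon)^2),  # on the normalized-catalog scale
         n_mutations = n,
         low_confidence = n < min_mutations,
         aetiologies = aet[names(fractions)]),
    class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature fit over ", x$n_mutations, " SNVs",
      if (x$low_confidence) " [low confidence]", "\n", sep = "")
  ord <- order(x$fractions, decreasing = TRUE)
  for (i in ord)
    cat(sprintf("  %-8s %5.1f%%  (%s)\n", names(x$fractions)[i],
                100 * x$fractions[i], x$aetiologies[i]))
  cat("  reconstruction cosine: ", round(x$reconstruction_cosine, 4), "\n",
      sep = "")
  invisible(x)
}

#' Compute tumor mutational burden
#'
#' Counts variants passing the consequence filter (protein-altering, i.e.
#' impact HIGH or MODERATE, plus splice-region terms) and divides by the
#' size of the interrogated coding territory in megabases.
#'
#' @param variants Variant table.
#' @param target_size_mb Coding target size in Mb (default 36.0).
#' @return Object of class `tmb_result`: `n_counted`, `target_size_mb`,
#'   `tmb` (mutations per Mb, exactly `n_counted / target_size_mb`).
#' @export
compute_tmb <- function(variants, target_size_mb = 36.0) {
  if (!is.numeric(target_size_mb) || target_size_mb <= 0)
    stop("target_size_mb must be > 0", call. = FALSE)
  qual <- tmb_qualifying(variants)
  n <- sum(qual)
  structure(list(n_counted = n, target_size_mb = target_size_mb,
                 tmb = n / target_size_mb),
            class = "tmb_result")
}

# protein-altering + splice consequence filter for the TMB numerator
tmb_qualifying <- function(variants) {
  variants$impact %in% c("HIGH", "MODERATE") |
    grepl("splice", variants$consequence, fixed = TRUE)
}

#' @export
print.tmb_result <- function(x, ...) {
  cat("TMB: ", format(x$tmb, digits = 4), " mutations/Mb (", x$n_counted,
      " qualifying variants / ", x$target_size_mb, " Mb)\n", sep = "")
  invisible(x)
}
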