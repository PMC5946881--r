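#' Train the microsatellite-instability classifier
#'
#' Fits a logistic model of MSI status on three whole-profile features:
#' indel fraction, indels per Mb and SNVs per Mb. MSI-high tumors arise from
#' mismatch-repair deficiency and show a markedly elevated indel burden,
#' which is what the features capture.
#'
#' @param cohort data.frame with columns `indel_fraction`, `indels_per_mb`,
#'   `snvs_per_mb` and `label` (values "MSI-high" and "MSS"; both classes
#'   must be present). See [simulate_msi_cohort()].
#' @param cutoff Probability cutoff mapping the score to MSI-high
#'   (default 0.5).
#' @return Object of class `msi_model`: coefficients, feature names, cutoff.
#' @export
train_msi_model <- function(cohort, cutoff = 0.5) {
  feats <- c("indel_fraction", "indels_per_mb", "snvs_per_mb")
  stopifnot(all(c(feats, "label") %in% names(cohort)))
  if (length(unique(cohort$label)) < 2L)
    stop("MSI training cohort contains a single class; need both MSI-high ",
         "and MSS examples", call. = FALSE)
  y <- as.integer(cohort$label == "MSI-high")
  # the classes separate almost perfectly by construction; glm's perfect-
  # separation warning is expected and benign here
  fit <- suppressWarnings(
    stats::glm(y ~ indel_fraction + indels_per_mb + snvs_per_mb,
               data = cohort, family = stats::binomial()))
  structure(list(coefficients = stats::coef(fit), features = feats,
                 cutoff = cutoff, n_train = nrow(cohort)),
            class = "msi_model")
}

#' @export
print.msi_model <- function(x, ...) {
  cat("MSI logistic classifier (", x$n_train, " training profiles, cutoff ",
      x$cutoff, ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

# logistic score for a feature row (named list/data.frame row)
msi_score <- function(model, features) {
  b <- model$coefficients
  eta <- b[[1]] + sum(vapply(seq_along(model$features), function(i)
    b[[i + 1L]] * features[[model$features[i]]], numeric(1)))
  stats::plogis(eta)
}

#' Serialize / load an MSI model as JSON
#'
#' @param model An `msi_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `msi_model_from_json` returns the model.
#' @export
msi_model_to_json <- function(model, path) {
  jsonlite::write_json(
    list(type = "msi_logistic", features = model$features,
         coefficients = as.list(model$coefficients),
         cutoff = model$cutoff, n_train = model$n_train),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname msi_model_to_json
#' @export
msi_model_from_json <- function(path) {
  j <- jsonlite::read_json(path)
  structure(list(coefficients = unlist(j$coefficients),
                 features = unlist(j$features),
                 cutoff = j$cutoff, n_train = j$n_train %||% NA_integer_),
            class = "msi_model")
}

#' Predict microsatellite instability from a variant profile
#'
#' Computes the three whole-profile features from PASS variants (indel
#' fraction over indels + SNVs; per-Mb rates over the coding target size),
#' scores them with the trained logistic model, and maps the probability to
#' MSI-high / MSS at the model cutoff. Samples with fewer than
#' `min_variants` variants are called `undetermined`.
#'
#' @param variants Variant table.
#' @param coding_target_mb Coding territory in Mb used for the rates.
#' @param model An `msi_model`.
#' @param min_variants Minimum variant count for a determinate call
#'   (default 20).
#' @return List of class `msi_prediction`: `status` ("MSI-high", "MSS" or
#'   "undetermined"), `probability`, `features`, `n_variants`.
#' @export
predict_msi <- function(variants, coding_target_mb, model, min_variants = 20L) {
  stopifnot(coding_target_mb > 0)
  n_indel <- sum(variants$variant_class %in% c("insertion", "deletion"))
  n_snv <- sum(variants$variant_class == "SNV")
  n <- nrow(variants)
  feats <- list(
    indel_fraction = if (n_indel + n_snv > 0) n_indel / (n_indel + n_snv)
                     else NA_real_,
    indels_per_mb = n_indel / coding_target_mb,
    snvs_per_mb = n_snv / coding_target_mb)
  prob <- if (is.na(feats$indel_fraction)) NA_real_ else msi_score(model, feats)
  status <- if (n < min_variants) "undetermined"
            else if (prob >= model$cutoff) "MSI-high" else "MSS"
  structure(list(status = status, probability = prob, features = feats,
                 n_variants = n), class = "msi_prediction")
}

#' @export
print.msi_prediction <- function(x, ...) {
  cat("MSI prediction: ", x$status,
      if (!is.na(x$probability))
        paste0(" (P[MSI-high] = ", round(x$probability, 3), ")"),
      "\n  indel fraction ", round(x$features$indel_fraction, 3),
      ", indels/Mb ", round(x$features$indels_per_mb, 2),
      ", SNVs/Mb ", round(x$features$snvs_per_mb, 2),
      " over ", x$n_variants, " variants\n", sep = "")
  invisible(x)
}
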