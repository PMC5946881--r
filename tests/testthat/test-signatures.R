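test_that("an exactly representable catalog recovers one signature with cosine 1", {
  W <- withr::with_seed(5L, random_signature_matrix(3L))
  y <- W[, 2] * 400  # exactly a scaled column of SIG2
  fit <- fit_signatures(stats::setNames(y, rownames(W)), W)
  expect_equal(names(fit$fractions), "SIG2")
  expect_equal(unname(fit$fractions), 1)
  expect_equal(fit$reconstruction_cosine, 1, tolerance = 1e-9)
})

test_that("signature fractions recover a known mixture from multinomial draws", {
  W <- withr::with_seed(77L, random_signature_matrix(3L, separated = TRUE))
  truth <- c(0.6, 0.3, 0.1)
  err <- withr::with_seed(78L, replicate(20, {
    counts <- stats::rmultinom(1, 2000, W %*% truth)[, 1]
    fit <- fit_signatures(stats::setNames(counts, rownames(W)), W)
    fr <- fit$fractions[colnames(W)]
    fr[is.na(fr)] <- 0
    mean(abs(fr - truth))
  }))
  expect_lt(mean(err), 0.05)
})

test_that("a dominant signature is identified from 1000 single-signature draws", {
  W <- withr::with_seed(80L, random_signature_matrix(4L, separated = TRUE))
  ok <- withr::with_seed(81L, replicate(20, {
    counts <- stats::rmultinom(1, 1000, W[, 1])[, 1]
    fit <- fit_signatures(stats::setNames(counts, rownames(W)), W)
    isTRUE(fit$fractions["SIG1"] >= 0.95)
  }))
  expect_true(all(ok))
})

test_that("the NNLS fit beats every single-signature least-squares fit", {
  # brute-force oracle: best unconstrained single-signature scaling
  single_residual <- function(y, w) {
    b <- sum(y * w) / sum(w * w)
    sum((y - b * w)^2)
  }
  set.seed(90)
  for (rep in 1:20) {
    W <- random_signature_matrix(5L)
    counts <- stats::rmultinom(1, 500,
                               W %*% as.numeric(stats::runif(5)))[, 1]
    fit <- fit_signatures(stats::setNames(counts, rownames(W)), W,
                          prune_threshold = 0)
    y <- counts / sum(counts)
    for (k in 1:5)
      expect_lte(fit$residual, single_residual(y, W[, k]) + 1e-12)
  }
})

test_that("pruning removes trace signatures and renormalizes to one", {
  W <- withr::with_seed(6L, random_signature_matrix(4L, separated = TRUE))
  y <- as.numeric(W %*% c(0.65, 0.32, 0.02, 0.01)) * 1000
  fit <- fit_signatures(stats::setNames(y, rownames(W)), W,
                        prune_threshold = 0.06)
  expect_setequal(names(fit$fractions), c("SIG1", "SIG2"))
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-6)
  expect_true(all(fit$fractions >= 0.06))
})

test_that("degenerate inputs are handled: zero catalog errors, low counts flagged", {
  W <- withr::with_seed(7L, random_signature_matrix(2L))
  zero <- stats::setNames(integer(96), rownames(W))
  expect_error(fit_signatures(zero, W), "no SNVs")
  small <- stats::setNames(stats::rmultinom(1, 10, W[, 1])[, 1], rownames(W))
  fit <- withr::with_seed(8L, fit_signatures(small, W, min_mutations = 50))
  expect_true(fit$low_confidence)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-6)
})

test_that("TMB is the qualifying count over the target size, linear in variants", {
  v <- data.frame(impact = c(rep("MODERATE", 4), rep("LOW", 4), "HIGH", "MODIFIER"),
                  consequence = c(rep("missense_variant", 4),
                                  rep("synonymous_variant", 3),
                                  "splice_acceptor_variant",
                                  "stop_gained", "intron_variant"),
                  stringsAsFactors = FALSE)
  # by hand: 4 missense + 1 splice + 1 stop_gained = 6 qualifying
  tmb <- compute_tmb(v, 36.0)
  expect_equal(tmb$n_counted, 6L)
  expect_equal(tmb$tmb, 6 / 36)
  expect_equal(compute_tmb(v[0, ], 36)$tmb, 0)
  expect_equal(compute_tmb(rbind(v, v), 36)$tmb, 2 * tmb$tmb)
  expect_error(compute_tmb(v, 0), "target_size_mb")
  v72 <- data.frame(impact = rep("HIGH", 72), consequence = "stop_gained",
                    stringsAsFactors = FALSE)
  expect_equal(compute_tmb(v72, 36)$tmb, 2)
})
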