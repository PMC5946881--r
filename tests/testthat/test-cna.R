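test_that("segments are called gain/loss/none at the log2 thresholds", {
  seg <- data.frame(chrom = "1", start = c(1L, 100L, 200L),
                    end = c(50L, 150L, 250L),
                    log2_ratio = c(1.6, -2.3, 0.2), stringsAsFactors = FALSE)
  called <- call_segments(seg)
  expect_equal(called$call, c("gain", "loss", NA))
  expect_equal(call_segments(seg, gain_log2 = 0.1)$call[3], "gain")
  expect_error(call_segments(seg, loss_log2 = 0.5), "loss_log2 < 0")
})

test_that("overlap arithmetic is inclusive-coordinate exact", {
  b <- shared_bundle()
  g <- b$genes[1, ]
  # segment overlapping the transcript tail: hand-checked inclusive span
  seg <- data.frame(chrom = g$chrom, start = g$span_start - 50L,
                    end = g$span_start + 50L, log2_ratio = 1.5,
                    stringsAsFactors = FALSE)
  ev <- intersect_genes(call_segments(seg), b)
  hit <- ev[ev$gene_symbol == g$gene_symbol, ]
  expect_equal(hit$overlap_bp, 51L)
  span_len <- g$span_end - g$span_start + 1L
  expect_equal(hit$overlap_fraction, 51L / span_len)
  # segment entirely inside the transcript
  seg2 <- data.frame(chrom = g$chrom, start = g$span_start + 10L,
                     end = g$span_start + 29L, log2_ratio = -2,
                     stringsAsFactors = FALSE)
  ev2 <- intersect_genes(call_segments(seg2), b)
  expect_equal(ev2$overlap_bp, 20L)
  expect_equal(ev2$overlap_fraction, 20L / span_len)
  expect_equal(ev2$call, "loss")
  # disjoint segment yields no event
  seg3 <- data.frame(chrom = "99", start = 1L, end = 100L, log2_ratio = 2,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_genes(call_segments(seg3), b)), 0L)
})

test_that("interval intersection matches the brute-force all-pairs oracle", {
  set.seed(55)
  n_seg <- 300L
  n_gene <- 150L
  genes <- data.frame(
    gene_symbol = sprintf("G%04d", seq_len(n_gene)),
    chrom = sample(c("1", "2", "3"), n_gene, replace = TRUE),
    span_start = sample.int(1e6L, n_gene), stringsAsFactors = FALSE)
  genes$span_end <- genes$span_start + sample.int(5e4L, n_gene)
  genes$literature_score <- runif(n_gene)
  seg <- data.frame(
    chrom = sample(c("1", "2", "3"), n_seg, replace = TRUE),
    start = sample.int(1e6L, n_seg), stringsAsFactors = FALSE)
  seg$end <- seg$start + sample.int(1e5L, n_seg)
  seg$log2_ratio <- sample(c(2, -2), n_seg, replace = TRUE)
  seg$call <- ifelse(seg$log2_ratio > 0, "gain", "loss")
  bundle <- list(genes = genes,
                 evidence = data.frame(id = character(),
                                       gene_symbol = character(),
                                       has_allele = logical(),
                                       stringsAsFactors = FALSE))
  got <- intersect_genes(seg, bundle)
  oracle <- brute_force_overlap(seg, genes)
  key_got <- sort(paste(got$gene_symbol, got$seg_start, got$seg_end,
                        got$overlap_bp))
  key_orc <- sort(paste(oracle$gene, seg$start[oracle$seg],
                        seg$end[oracle$seg], oracle$overlap_bp))
  expect_identical(key_got, key_orc)
  # symmetry: the transposed scan yields the same pair set
  tr <- brute_force_overlap(
    data.frame(chrom = genes$chrom, start = genes$span_start,
               end = genes$span_end, stringsAsFactors = FALSE),
    data.frame(gene_symbol = as.character(seq_len(n_seg)), chrom = seg$chrom,
               span_start = seg$start, span_end = seg$end,
               stringsAsFactors = FALSE))
  expect_equal(nrow(tr), nrow(oracle))
})

test_that("events sort by call then descending literature score", {
  b <- shared_bundle()
  seg <- data.frame(chrom = "1", start = 1L,
                    end = sum(Biostrings::width(b$genome)),
                    log2_ratio = c(1.2, -1.2), stringsAsFactors = FALSE)
  seg <- rbind(seg[1, ], seg[1, ])
  seg$log2_ratio <- c(1.2, -1.2)
  ev <- intersect_genes(call_segments(seg), b)
  expect_true(all(ev$call[ev$call == "gain"] ==
                  head(ev$call, sum(ev$call == "gain"))))
  gains <- ev[ev$call == "gain", ]
  expect_true(all(diff(gains$literature_score) <= 0))
})
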