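#' Call gains and losses on copy-number segments
#'
#' Labels each segment by its log2 ratio: `gain` at or above `gain_log2`,
#' `loss` at or below `loss_log2`; segments in between carry no call and are
#' excluded from event calling (they are retained in the report appendix).
#'
#' @param segments Segment table ([read_cna_segments()]).
#' @param gain_log2,loss_log2 Thresholds (defaults +0.8 / -0.8; must bracket
#'   zero).
#' @return The table with a `call` column ("gain", "loss" or NA).
#' @export
call_segments <- function(segments, gain_log2 = 0.8, loss_log2 = -0.8) {
  stopifnot(loss_log2 < 0, gain_log2 > 0)
  call <- rep(NA_character_, nrow(segments))
  call[segments$log2_ratio >= gain_log2] <- "gain"
  call[segments$log2_ratio <= loss_log2] <- "loss"
  segments$call <- call
  segments
}

#' Intersect called segments with gene transcripts
#'
#' Produces one event per (gene transcript, called segment) pair with at
#' least 1 bp of overlap, using 1-based inclusive coordinates. The overlap
#' fraction is overlap_bp / transcript span length so downstream users can
#' filter; no minimum fraction is imposed. Gene-granularity evidence items
#' (e.g. amplification-predictive assertions) are attached per gene. Events
#' are sorted by call ("gain" before "loss") then descending literature
#' score.
#'
#' @param segments Called segment table ([call_segments()]).
#' @param bundle Loaded bundle (gene spans + evidence).
#' @return data.frame of events: `gene_symbol`, `chrom`, `seg_start`,
#'   `seg_end`, `log2_ratio`, `call`, `overlap_bp`, `overlap_fraction`,
#'   `literature_score`, `n_gene_evidence`, `evidence_ids`.
#' @export
intersect_genes <- function(segments, bundle) {
  seg <- segments[!is.na(segments$call), , drop = FALSE]
  genes <- bundle$genes
  empty <- data.frame(gene_symbol = character(), chrom = character(),
                      seg_start = integer(), seg_end = integer(),
                      log2_ratio = numeric(), call = character(),
                      overlap_bp = integer(), overlap_fraction = numeric(),
                      literature_score = numeric(),
                      n_gene_evidence = integer(), evidence_ids = character(),
                      stringsAsFactors = FALSE)
  if (nrow(seg) == 0L || nrow(genes) == 0L) return(empty)

  gr_seg <- GenomicRanges::GRanges(
    seg$chrom, IRanges::IRanges(seg$start, seg$end))
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$span_start, genes$span_end))
  # disjoint seqlevels between segments and genes are legitimate (no shared
  # chromosome simply means no events), so the seqlevel warning is muted
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_seg, gr_gene))
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_seg)[qi],
                                           IRanges::ranges(gr_gene)[si]))
  span_len <- genes$span_end[si] - genes$span_start[si] + 1L

  ev_gene <- bundle$evidence[!bundle$evidence$has_allele, , drop = FALSE]
  gene_ev <- function(sym) ev_gene$id[ev_gene$gene_symbol == sym]

  out <- data.frame(
    gene_symbol = genes$gene_symbol[si],
    chrom = seg$chrom[qi],
    seg_start = seg$start[qi], seg_end = seg$end[qi],
    log2_ratio = seg$log2_ratio[qi], call = seg$call[qi],
    overlap_bp = ov, overlap_fraction = ov / span_len,
    literature_score = genes$literature_score[si],
    stringsAsFactors = FALSE)
  ev_ids <- lapply(out$gene_symbol, gene_ev)
  out$n_gene_evidence <- lengths(ev_ids)
  out$evidence_ids <- vapply(ev_ids, function(x)
    paste(sort(x), collapse = ","), character(1))
  out <- out[order(match(out$call, c("gain", "loss")),
                   -out$literature_score, out$gene_symbol, out$seg_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
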