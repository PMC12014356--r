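#' @importFrom IRanges findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Reciprocal overlap of two genomic intervals
#'
#' The reciprocal overlap of intervals `a` and `b` is
#' `min(ov / len(a), ov / len(b))` where `ov` is the length of their
#' intersection in bp; it is 1 iff the intervals are identical and 0 when
#' they are disjoint or on different chromosomes (no error is raised).
#' Vectorized elementwise over equal-length `GRanges`.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' reciprocalOverlap(a, b)  # 0.5
#' @export
reciprocalOverlap <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  ov <- pmax(0, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1)
  ov[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0
  pmin(ov / width(a), ov / width(b))
}

#' Per-call carrier count and sample frequency
#'
#' For each call, counts the distinct samples carrying a CNV of the same
#' type with reciprocal overlap at or above `ro_threshold` (the carrier
#' itself always counts), and divides by the total number of samples in
#' the call set — the "sample frequency" used for the <1% rarity filter.
#'
#' @param x a [CnvCallSet-class].
#' @param ro_threshold reciprocal-overlap threshold defining "the same"
#'   CNV (default 0.5, i.e. 50% reciprocal overlap).
#' @return `data.frame` parallel to `cnvCalls(x)` with columns `count`
#'   and `frequency`.
#' @export
cnvFrequency <- function(x, ro_threshold = 0.5) {
  gr <- cnvCalls(x)
  n <- nSamples(x)
  if (!length(gr))
    return(data.frame(count = integer(), frequency = numeric()))
  hits <- findOverlaps(gr, gr)
  q <- queryHits(hits); s <- subjectHits(hits)
  keep <- mcols(gr)$cnv_type[q] == mcols(gr)$cnv_type[s]
  q <- q[keep]; s <- s[keep]
  ro <- reciprocalOverlap(gr[q], gr[s])
  keep <- ro >= ro_threshold
  q <- q[keep]; s <- s[keep]
  key <- paste0(q, "\r", mcols(gr)$sample_id[s])
  dup <- duplicated(key)
  cnt <- tabulate(q[!dup], nbins = length(gr))
  data.frame(count = cnt, frequency = cnt / n)
}

.append_filter_log <- function(x, record) {
  log <- metadata(x@calls)$filter_log
  metadata(x@calls)$filter_log <- c(log, list(record))
  x
}

#' Retrieve the filter log of a call set
#'
#' Each QC/rarity filtering step appends a record (`step`, `n_before`,
#' `n_removed`, `n_after`) to the call set.
#' @param x a `CnvCallSet`.
#' @return list of filter records (possibly empty).
#' @export
filterLog <- function(x) {
  log <- metadata(cnvCalls(x))$filter_log
  if (is.null(log)) list() else log
}

#' Quality-control filter on call length and probe support
#'
#' Retains calls strictly longer than `min_length` bp that are supported
#' by at least `min_probes` array probes; the defaults keep calls longer
#' than 20 kb with 10 or more probes. A call of exactly `min_length` bp is
#' removed. Idempotent; the removed count is appended to [filterLog()].
#'
#' @param x a [CnvCallSet-class].
#' @param min_length minimum length in bp (exclusive bound).
#' @param min_probes minimum probe count (inclusive bound).
#' @return the filtered `CnvCallSet`.
#' @export
qcFilter <- function(x, min_length = 20000, min_probes = 10L) {
  gr <- cnvCalls(x)
  keep <- width(gr) > min_length & mcols(gr)$n_probes >= min_probes
  out <- .replaceCalls(x, gr[keep])
  .append_filter_log(out, list(step = "qc", n_before = length(gr),
                               n_removed = sum(!keep),
                               n_after = sum(keep)))
}

#' Rarity filter at a sample-frequency threshold
#'
#' Retains calls whose sample frequency (see [cnvFrequency()]) is strictly
#' below `max_freq`; the default keeps rare CNVs with frequency < 1%.
#' Idempotent for fixed carrier structure; the removed count is appended
#' to [filterLog()].
#'
#' @inheritParams cnvFrequency
#' @param max_freq frequency bound (exclusive).
#' @return the filtered `CnvCallSet`.
#' @export
filterRare <- function(x, max_freq = 0.01, ro_threshold = 0.5) {
  gr <- cnvCalls(x)
  if (!length(gr)) return(.append_filter_log(x, list(
    step = "rare", n_before = 0L, n_removed = 0L, n_after = 0L)))
  fr <- cnvFrequency(x, ro_threshold = ro_threshold)
  keep <- fr$frequency < max_freq
  out <- .replaceCalls(x, gr[keep])
  .append_filter_log(out, list(step = "rare", n_before = length(gr),
                               n_removed = sum(!keep),
                               n_after = sum(keep)))
}
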