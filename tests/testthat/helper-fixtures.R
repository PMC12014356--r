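suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# build a CnvCallSet from a compact call table; every referenced sample
# plus `extra_samples` anonymous controls enter the sample table
toyCallSet <- function(calls, n_extra_controls = 0, status = NULL,
                       cohort = NULL, pc1 = NULL) {
  k <- nrow(calls)
  gr <- GRanges(calls$chrom, IRanges(calls$start, calls$end),
                sample_id = calls$sample_id, cnv_type = calls$cnv_type,
                n_probes = if ("n_probes" %in% names(calls))
                  calls$n_probes else rep(20L, k),
                score = rep(30, k))
  ids <- unique(calls$sample_id)
  if (n_extra_controls > 0)
    ids <- c(ids, sprintf("X%04d", seq_len(n_extra_controls)))
  n <- length(ids)
  smp <- data.frame(
    sample_id = ids,
    status = if (is.null(status)) rep(0L, n) else status,
    sex = "F",
    cohort = if (is.null(cohort)) rep("c1", n) else cohort,
    pc1 = if (is.null(pc1)) rep(0, n) else pc1,
    stringsAsFactors = FALSE)
  CnvCallSet(gr, smp, genome = "toy")
}

# a deterministic probe map with one probe every `by` bp
toyProbes <- function(chrom = "chr1", to = 2e6, by = 2000) {
  pos <- seq(by, to, by = by)
  GRanges(chrom, IRanges(pos, width = 1L),
          probe_id = paste0("p", seq_along(pos)))
}

# independent penalized log-likelihood (Firth objective) for a 2x2
# table coded as counts (a,b,c,d) = exposed cases/controls,
# unexposed cases/controls; used as an oracle against the package fit
plik2x2 <- function(b0, b1, a, b, c, d) {
  x <- c(1, 1, 0, 0)
  y <- c(1, 0, 1, 0)
  w <- c(a, b, c, d)
  eta <- b0 + b1 * x
  p <- plogis(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(w * (y * log(p) + (1 - y) * log(1 - p)))
  ww <- w * p * (1 - p)
  X <- cbind(1, x)
  info <- t(X) %*% (ww * X)
  ll + 0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
}

# grid-then-refine maximizer of the penalized likelihood profile in the
# log-OR; independent of the package's Newton-Raphson path
gridMaxLogOr <- function(a, b, c, d, lo = -8, hi = 8) {
  prof <- function(b1)
    optimize(function(b0) plik2x2(b0, b1, a, b, c, d),
             c(-12, 12), maximum = TRUE, tol = 1e-9)$objective
  grid <- seq(lo, hi, length.out = 161)
  vals <- vapply(grid, prof, 0)
  i <- which.max(vals)
  optimize(prof, c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
           maximum = TRUE, tol = 1e-9)$maximum
}

haldaneLogOr <- function(a, b, c, d)
  log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
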