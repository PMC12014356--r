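#' Null-calibration simulation study
#'
#' Runs replicate synthetic studies with every planted odds ratio equal
#' to 1 (no case-control signal anywhere) and collects null p-values
#' from the three association layers: the covariate-adjusted logistic
#' burden test of total CNV count (one p per replicate, one-sided), the
#' per-locus Firth tests over the planted null loci, and the breakpoint
#' scan (one breakpoint per planted locus per model, taken nearest the
#' locus midpoint). Results carry the replicate index so a caller can
#' keep one draw per replicate, giving exactly independent draws for
#' binomial calibration bounds. Planted null loci use a carrier
#' frequency of 0.8% so
#' that each test rests on roughly 15 carriers — the regime where a 5%
#' nominal rate is a meaningful calibration target; sparser exposures
#' make any penalized-likelihood test conservative by discreteness.
#'
#' Each replicate simulates `n_cases + n_controls` samples on a reduced
#' three-chromosome genome (530 Mb); background CNV rates, lengths and
#' covariate structure keep the generator defaults.
#'
#' @param n_reps number of replicate studies.
#' @param n_cases,n_controls per-replicate sample sizes.
#' @param n_loci number of planted null loci.
#' @param carrier_freq control carrier frequency of the planted loci.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return list with `burden_p` (numeric, one per replicate) and
#'   `locus` / `scan` data.frames (`rep`, `locus`, `p`).
#' @export
nullCalibrationStudy <- function(n_reps = 200, n_cases = 1190,
                                 n_controls = 810, n_loci = 10,
                                 carrier_freq = 0.008, seed = 1L) {
  chroms <- c(chr1 = 2e8, chr2 = 1.8e8, chr3 = 1.5e8)
  pos <- seq(2e7, 1.4e8, length.out = ceiling(n_loci / 2))
  planted <- data.frame(
    chrom = rep(c("chr1", "chr2"), each = ceiling(n_loci / 2)),
    start = round(rep(pos, 2)),
    end = round(rep(pos, 2)) + 1e5,
    cnv_type = rep(c("DEL", "DUP"), length.out = 2 * ceiling(n_loci / 2)),
    carrier_freq_controls = carrier_freq, odds_ratio = 1,
    jitter_sd = 5000, stringsAsFactors = FALSE)[seq_len(n_loci), ]
  burden_p <- numeric(0)
  locus <- list(); scan <- list()
  for (r in seq_len(n_reps)) {
    cfg <- simConfig(n_cases = n_cases, n_controls = n_controls,
                     chrom_lengths = chroms, planted_loci = planted,
                     n_recurrent_null = 0, n_syndromic = n_loci,
                     n_pleiotropic = 1, seed = seed + r)
    sim <- simulateCnvData(cfg)
    cs_qc <- qcFilter(sim$callset)
    cs <- filterRare(cs_qc)
    smp <- sampleTable(cs)
    prof <- suppressWarnings(burdenProfiles(cs))
    bt <- burdenTest(prof, smp, "n_cnv", sided = "one")
    if (bt$status == "tested") burden_p <- c(burden_p, bt$p_sided)
    ls <- locusScan(cs, sim$syndromic[seq_len(n_loci)], ci = "none")
    tested <- which(ls$status == "tested")
    if (length(tested))
      locus[[length(locus) + 1L]] <- data.frame(
        rep = r, locus = tested, p = ls$p_two_sided[tested])
    for (model in c("dup_only", "del_only")) {
      mtype <- if (model == "dup_only") "DUP" else "DEL"
      idx <- which(planted$cnv_type == mtype)
      if (!length(idx)) next
      bm <- filterRareBreakpoints(encodeBreakpoints(cs_qc, model))
      sc <- scanBreakpoints(bm, smp)
      for (i in idx) {
        mid <- (planted$start[i] + planted$end[i]) / 2
        in_seg <- which(sc$chrom == planted$chrom[i] &
                        sc$pos >= planted$start[i] &
                        sc$pos <= planted$end[i])
        if (!length(in_seg)) next
        j <- in_seg[which.min(abs(sc$pos[in_seg] - mid))]
        scan[[length(scan) + 1L]] <- data.frame(
          rep = r, locus = i, p = sc$p_two_sided[j])
      }
    }
  }
  list(burden_p = burden_p,
       locus = do.call(rbind, locus),
       scan = do.call(rbind, scan))
}

#' One independent draw per replicate from a calibration layer
#'
#' Reduces a replicate-indexed p-value table (from
#' [nullCalibrationStudy()]) to a single p-value per replicate — the
#' draw with the smallest locus index — so binomial calibration bounds
#' apply exactly.
#' @param df data.frame with `rep`, `locus`, `p`.
#' @return numeric vector, one p per replicate represented in `df`.
#' @export
onePerReplicate <- function(df) {
  df <- df[order(df$rep, df$locus), ]
  df$p[!duplicated(df$rep)]
}

#' Planted-CNVR recovery and mirror-detection simulation study
#'
#' Runs replicate studies at the full case-control sample size with two
#' planted deletion risk loci (100 kb, overall sample carrier frequency
#' 0.005, odds ratio 5), the second sharing its segment with a
#' protective duplication (odds ratio 1/5, control carrier frequency
#' 0.008) to form a mirror pair. Each replicate runs
#' QC, both CNV-type breakpoint scans with the <1% breakpoint rarity
#' filter, CNVR clumping, and the mirror scan, and records whether a
#' deletion-model CNVR overlapping the first planted segment was
#' emitted and whether a mirror pair was flagged within 300 kb of the
#' second. The genome is reduced to four chromosomes (~880 Mb) to keep
#' replicate studies tractable; sample size, rates and thresholds are
#' the study conditions.
#'
#' @param n_reps number of replicate studies.
#' @param n_cases,n_controls sample sizes.
#' @param odds_ratio planted-locus effect.
#' @param carrier_freq target OVERALL sample carrier frequency of each
#'   planted deletion locus (the quantity the <1% rarity filters
#'   check); the control frequency is back-solved from it under the
#'   case-control tilt.
#' @param seed base seed; replicate r uses `seed + 1000 + r`.
#' @return `data.frame` with one row per replicate: `recovered`
#'   (logical), `mirror_flagged` (logical), `n_cnvr_del`.
#' @export
cnvrRecoveryStudy <- function(n_reps = 50, n_cases = 7414,
                              n_controls = 5044, odds_ratio = 5,
                              carrier_freq = 0.005, seed = 1L) {
  chroms <- c(chr1 = 2.5e8, chr2 = 2.4e8, chr3 = 2e8, chr4 = 1.9e8)
  f0 <- .controlFreqForOverall(carrier_freq, odds_ratio,
                               n_cases, n_controls)
  planted <- data.frame(
    chrom = c("chr1", "chr2", "chr2"),
    start = c(5e7, 8e7, 8e7), end = c(5e7, 8e7, 8e7) + 1e5,
    cnv_type = c("DEL", "DEL", "DUP"),
    carrier_freq_controls = c(f0, f0, 0.008),
    odds_ratio = c(odds_ratio, odds_ratio, 1 / odds_ratio),
    jitter_sd = 20000, mirror = FALSE, stringsAsFactors = FALSE)
  target <- GRanges("chr1", IRanges(5e7, 5e7 + 1e5))
  out <- data.frame(rep = seq_len(n_reps), recovered = FALSE,
                    mirror_flagged = FALSE, n_cnvr_del = 0L)
  for (r in seq_len(n_reps)) {
    cfg <- simConfig(n_cases = n_cases, n_controls = n_controls,
                     chrom_lengths = chroms, planted_loci = planted,
                     n_recurrent_null = 20, n_syndromic = 4,
                     n_pleiotropic = 1, seed = seed + 1000 + r)
    sim <- simulateCnvData(cfg)
    cs_qc <- qcFilter(sim$callset)
    smp <- sampleTable(cs_qc)
    scans <- list()
    cnvr_del <- NULL
    for (model in c("dup_only", "del_only")) {
      bm <- filterRareBreakpoints(encodeBreakpoints(cs_qc, model))
      sc <- scanBreakpoints(bm, smp)
      scans[[model]] <- sc
      if (model == "del_only")
        cnvr_del <- clumpCnvrs(sc, bm, cs_qc, sim$probes)
    }
    if (nrow(cnvr_del)) {
      spans <- GRanges(cnvr_del$chrom,
                       IRanges(cnvr_del$start, cnvr_del$end))
      out$recovered[r] <- any(countOverlaps(spans, target) > 0)
      out$n_cnvr_del[r] <- nrow(cnvr_del)
    }
    mir <- mirrorScan(scans$dup_only, scans$del_only)
    out$mirror_flagged[r] <- any(mir$chrom == "chr2" &
                                 abs(mir$del_pos - 8.005e7) <= 3e5)
  }
  out
}

# control carrier frequency whose case-control mixture has the target
# overall sample frequency under an odds-ratio tilt
.controlFreqForOverall <- function(target, or, n_cases, n_controls) {
  n <- n_cases + n_controls
  f <- function(f0) {
    f1 <- or * f0 / (1 - f0 + or * f0)
    (n_cases * f1 + n_controls * f0) / n - target
  }
  stats::uniroot(f, c(1e-8, target), tol = 1e-10)$root
}
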