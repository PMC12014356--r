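#' @importFrom stats qlnorm plnorm
NULL

# approximate hg38 autosome + X lengths (bp)
.HG38_CHROM_LENGTHS <- c(
  chr1 = 248956000, chr2 = 242194000, chr3 = 198296000,
  chr4 = 190215000, chr5 = 181538000, chr6 = 170806000,
  chr7 = 159346000, chr8 = 145139000, chr9 = 138395000,
  chr10 = 133797000, chr11 = 135087000, chr12 = 133275000,
  chr13 = 114364000, chr14 = 107044000, chr15 = 101991000,
  chr16 = 90338000, chr17 = 83258000, chr18 = 80373000,
  chr19 = 58618000, chr20 = 64444000, chr21 = 46710000,
  chr22 = 50818000, chrX = 156041000)

#' Configuration for the synthetic CNV study generator
#'
#' Bundles every tunable of [simulateCnvData()] with defaults that
#' emulate a large array-based CNV case-control study: 7414 cases and
#' 5044 controls; background CNV counts Poisson with means 0.9
#' duplications and 0.7 deletions per sample; log-normal call lengths
#' with median 102.8 kb; probes roughly every 2.5 kb; two cohorts with
#' different case/control composition; a standard-normal ancestry PC
#' with a weak positive effect on small (<100 kb) CNV counts; and
#' case/control lowest-BMI distributions. Background CNVs are drawn
#' independently of case-control status, so global burden is null by
#' construction unless `case_rate_multiplier != 1`.
#'
#' Recurrent risk loci are planted via `planted_loci`, a `data.frame`
#' with columns `chrom`, `start`, `end`, `cnv_type`, ­
#' `carrier_freq_controls`, `odds_ratio`, `jitter_sd` and optionally
#' `mirror` (logical; adds an opposite-type partner at the same segment
#' with the reciprocal odds ratio) and `bmi_effect` (kg/m^2 added to
#' carriers' lowest BMI). Carrier probability in cases is tilted on the
#' odds scale: `f1 = OR*f0 / (1 - f0 + OR*f0)`. Carriers receive a call
#' covering the segment with endpoints jittered outward by
#' `|N(0, jitter_sd)|`, emulating recurrent CNVs; `n_recurrent_null`
#' additional null recurrent loci (odds ratio 1) provide a realistic
#' carrier-frequency spectrum. Everything is drawn from `seed` alone.
#'
#' @param n_cases,n_controls sample sizes.
#' @param dup_rate,del_rate mean background duplications/deletions per
#'   sample.
#' @param length_meanlog,length_sdlog log-normal call-length parameters
#'   (defaults give median 102.8 kb).
#' @param probe_spacing mean bp between probes.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param cohort_case_frac,cohort_control_frac probability of cohort
#'   `"cohort1"` membership for cases/controls.
#' @param pc1_small_burden_effect log-linear effect of PC1 on the
#'   <100 kb background CNV rate.
#' @param case_rate_multiplier multiplier on background CNV rates in
#'   cases (1 = null burden).
#' @param planted_loci `data.frame` of planted loci (see Details), or
#'   `NULL`.
#' @param n_recurrent_null number of null recurrent background loci.
#' @param female_frac_cases,female_frac_controls sex composition.
#' @param bmi_case_mean,bmi_case_sd,bmi_control_mean,bmi_control_sd
#'   lowest-BMI distributions (kg/m^2).
#' @param gene_density_per_mb protein-coding gene density.
#' @param frac_haplo,frac_triplo fraction of genes forced above the
#'   haploinsufficiency (0.86) / triplosensitivity (0.94) score
#'   thresholds.
#' @param constrained_frac fraction of the genome covered by highly
#'   constrained elements in each constraint track.
#' @param n_syndromic,n_pleiotropic locus-list sizes (planted loci are
#'   included, the remainder are decoy segments).
#' @param seed integer seed; fully determines the output.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(n_cases = 7414, n_controls = 5044,
                      dup_rate = 0.9, del_rate = 0.7,
                      length_meanlog = log(102800), length_sdlog = 0.8,
                      probe_spacing = 2500,
                      chrom_lengths = .HG38_CHROM_LENGTHS,
                      cohort_case_frac = 0.494,
                      cohort_control_frac = 0.726,
                      pc1_small_burden_effect = 0.05,
                      case_rate_multiplier = 1,
                      planted_loci = NULL,
                      n_recurrent_null = 30,
                      female_frac_cases = 0.98,
                      female_frac_controls = 0.94,
                      bmi_case_mean = 15.2, bmi_case_sd = 2.1,
                      bmi_control_mean = 20.9, bmi_control_sd = 2.0,
                      gene_density_per_mb = 6.5,
                      frac_haplo = 0.16, frac_triplo = 0.07,
                      constrained_frac = 0.0326,
                      n_syndromic = 67, n_pleiotropic = 178,
                      seed = 1L) {
  stopifnot(dup_rate >= 0, del_rate >= 0, n_cases > 0, n_controls > 0,
            probe_spacing > 0, constrained_frac >= 0,
            constrained_frac < 1)
  if (!is.null(planted_loci)) {
    planted_loci <- as.data.frame(planted_loci)
    need <- c("chrom", "start", "end", "cnv_type",
              "carrier_freq_controls", "odds_ratio")
    if (!all(need %in% colnames(planted_loci)))
      stop("planted_loci needs columns: ", paste(need, collapse = ", "))
    if (!"jitter_sd" %in% colnames(planted_loci))
      planted_loci$jitter_sd <- 5000
    if (!"mirror" %in% colnames(planted_loci))
      planted_loci$mirror <- FALSE
    if (!"bmi_effect" %in% colnames(planted_loci))
      planted_loci$bmi_effect <- 0
    stopifnot(all(planted_loci$odds_ratio > 0),
              all(planted_loci$carrier_freq_controls > 0),
              all(planted_loci$start < planted_loci$end))
    gr <- GRanges(planted_loci$chrom,
                  IRanges(planted_loci$start, planted_loci$end))
    for (tp in .VALID_CNV_TYPES) {
      g <- gr[planted_loci$cnv_type == tp]
      if (length(g) > 1L) {
        h <- findOverlaps(g, g)
        if (any(queryHits(h) != subjectHits(h)))
          stop("planted loci of the same type overlap")
      }
    }
  }
  structure(as.list(environment()), class = "SimConfig")
}

.sim_samples <- function(cfg) {
  n <- cfg$n_cases + cfg$n_controls
  status <- rep(c(1L, 0L), c(cfg$n_cases, cfg$n_controls))
  DataFrame(
    sample_id = sprintf("S%05d", seq_len(n)),
    status = status,
    sex = ifelse(runif(n) < ifelse(status == 1L, cfg$female_frac_cases,
                                   cfg$female_frac_controls), "F", "M"),
    cohort = ifelse(runif(n) < ifelse(status == 1L, cfg$cohort_case_frac,
                                      cfg$cohort_control_frac),
                    "cohort1", "cohort2"),
    pc1 = rnorm(n),
    bmi_lowest = ifelse(status == 1L,
                        rnorm(n, cfg$bmi_case_mean, cfg$bmi_case_sd),
                        rnorm(n, cfg$bmi_control_mean, cfg$bmi_control_sd)),
    age = round(ifelse(status == 1L, rnorm(n, 15.6, 4.4),
                       rnorm(n, 21.1, 8.2)), 1))
}

# background CNVs for one type; PC1 tilts the small-call (<100 kb) rate
.sim_background <- function(cfg, smp, type, rate) {
  n <- nrow(smp)
  p_small <- plnorm(1e5, cfg$length_meanlog, cfg$length_sdlog)
  tilt <- exp(cfg$pc1_small_burden_effect * smp$pc1)
  mult <- ifelse(smp$status == 1L, cfg$case_rate_multiplier, 1)
  m <- (p_small * tilt + (1 - p_small)) * mult
  counts <- rpois(n, rate * m)
  if (!sum(counts)) return(NULL)
  si <- rep.int(seq_len(n), counts)
  p_sm <- (p_small * tilt[si]) / m[si] * mult[si]
  small <- runif(length(si)) < p_sm
  # inverse-CDF draw from the small / large part of the log-normal
  u <- ifelse(small, runif(length(si), 0, p_small),
              runif(length(si), p_small, 1))
  len <- pmax(1000, round(qlnorm(u, cfg$length_meanlog, cfg$length_sdlog)))
  cl <- cfg$chrom_lengths
  chrom <- sample(names(cl), length(si), replace = TRUE,
                  prob = cl / sum(cl))
  maxs <- pmax(1, cl[chrom] - len)
  start <- 1 + floor(runif(length(si)) * maxs)
  data.frame(sample_id = smp$sample_id[si], chrom = chrom,
             start = start, end = pmin(start + len - 1, cl[chrom]),
             cnv_type = type, stringsAsFactors = FALSE)
}

# carriers of one recurrent locus get a jittered covering call
.sim_locus_calls <- function(cfg, smp, locus) {
  f0 <- locus$carrier_freq_controls
  or <- locus$odds_ratio
  f1 <- or * f0 / (1 - f0 + or * f0)
  p <- ifelse(smp$status == 1L, f1, f0)
  idx <- which(runif(nrow(smp)) < p)
  if (!length(idx)) return(NULL)
  jit <- locus$jitter_sd
  s <- locus$start - round(abs(rnorm(length(idx), 0, jit)))
  e <- locus$end + round(abs(rnorm(length(idx), 0, jit)))
  cl <- cfg$chrom_lengths[[locus$chrom]]
  data.frame(sample_id = smp$sample_id[idx], chrom = locus$chrom,
             start = pmax(1, s), end = pmin(e, cl),
             cnv_type = locus$cnv_type, stringsAsFactors = FALSE)
}

.expand_mirrors <- function(planted) {
  if (is.null(planted) || !nrow(planted)) return(planted)
  mir <- planted[planted$mirror, , drop = FALSE]
  if (!nrow(mir)) return(planted)
  partner <- mir
  partner$cnv_type <- ifelse(mir$cnv_type == "DEL", "DUP", "DEL")
  partner$odds_ratio <- 1 / mir$odds_ratio
  partner$mirror <- FALSE
  rbind(planted, partner)
}

#' Simulate a case-control CNV study
#'
#' Generates a complete synthetic study from a single seed: sample table
#' with covariates, background and planted recurrent CNV calls, probe
#' map, gene/exon annotations with dosage-sensitivity scores, constraint
#' tracks and syndromic/pleiotropic locus lists (via
#' [makeAnnotations()]). See [simConfig()] for what the defaults
#' emulate. Identical configurations (same seed) give identical output.
#'
#' @param cfg a [simConfig()] object.
#' @return list with elements `callset` ([CnvCallSet-class]), `probes`,
#'   `genes`, `exons`, `constraint` (list `phylop`/`phastcons`),
#'   `syndromic`, `pleiotropic` (locus `GRanges`) and `config`.
#' @export
simulateCnvData <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  smp <- .sim_samples(cfg)
  calls <- list(.sim_background(cfg, smp, "DUP", cfg$dup_rate),
                .sim_background(cfg, smp, "DEL", cfg$del_rate))
  # null recurrent background loci give the carrier-frequency spectrum
  rec <- NULL
  if (cfg$n_recurrent_null > 0) {
    cl <- cfg$chrom_lengths
    len <- pmax(30000, round(rlnorm(cfg$n_recurrent_null,
                                    cfg$length_meanlog, cfg$length_sdlog)))
    chrom <- sample(names(cl), cfg$n_recurrent_null, replace = TRUE,
                    prob = cl / sum(cl))
    start <- 1 + floor(runif(cfg$n_recurrent_null) *
                         pmax(1, cl[chrom] - len))
    rec <- data.frame(chrom = chrom, start = start,
                      end = pmin(start + len - 1, cl[chrom]),
                      cnv_type = sample(.VALID_CNV_TYPES,
                                        cfg$n_recurrent_null, TRUE),
                      carrier_freq_controls =
                        runif(cfg$n_recurrent_null, 5e-4, 8e-3),
                      odds_ratio = 1, jitter_sd = 2500,
                      stringsAsFactors = FALSE)
    calls <- c(calls, lapply(seq_len(nrow(rec)), function(i)
      .sim_locus_calls(cfg, smp, rec[i, ])))
  }
  planted <- .expand_mirrors(cfg$planted_loci)
  if (!is.null(planted) && nrow(planted))
    calls <- c(calls, lapply(seq_len(nrow(planted)), function(i)
      .sim_locus_calls(cfg, smp, planted[i, ])))
  calls <- do.call(rbind, calls[!vapply(calls, is.null, TRUE)])
  probes <- .sim_probes(cfg)
  gr <- GRanges(calls$chrom, IRanges(calls$start, calls$end),
                sample_id = calls$sample_id, cnv_type = calls$cnv_type,
                n_probes = 0L, score = round(runif(nrow(calls), 10, 50), 1))
  mcols(gr)$n_probes <- countOverlaps(gr, probes)
  gr <- gr[mcols(gr)$n_probes >= 1L]   # a call needs probe support
  # planted BMI effects on carriers
  if (!is.null(planted) && nrow(planted) &&
      any(planted$bmi_effect != 0)) {
    pl <- planted[planted$bmi_effect != 0, , drop = FALSE]
    plgr <- GRanges(pl$chrom, IRanges(pl$start, pl$end))
    for (i in seq_len(nrow(pl))) {
      hit <- gr[mcols(gr)$cnv_type == pl$cnv_type[i] &
                countOverlaps(gr, plgr[i]) > 0]
      idx <- smp$sample_id %in% mcols(hit)$sample_id
      smp$bmi_lowest[idx] <- smp$bmi_lowest[idx] + pl$bmi_effect[i]
    }
  }
  ann <- makeAnnotations(cfg)
  list(callset = CnvCallSet(gr, smp, genome = "synthetic"),
       probes = probes, genes = ann$genes, exons = ann$exons,
       constraint = ann$constraint, syndromic = ann$syndromic,
       pleiotropic = ann$pleiotropic, config = cfg)
}

.sim_probes <- function(cfg) {
  out <- lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    n <- ceiling(len / cfg$probe_spacing * 1.1) + 5
    pos <- cumsum(rpois(n, cfg$probe_spacing))
    pos <- pos[pos <= len]
    data.frame(chrom = ch, pos = pos,
               probe_id = paste0(ch, "_p", seq_along(pos)))
  })
  df <- do.call(rbind, out)
  GRanges(df$chrom, IRanges(df$pos, width = 1L), probe_id = df$probe_id)
}

#' Generate annotation inputs for a simulated study
#'
#' Draws (deterministically from `seed + 1`) the annotation side of the
#' study: protein-coding genes with `pHaplo`/`pTriplo` scores (uniform,
#' with configurable fractions forced above the 0.86 / 0.94
#' dosage-sensitivity thresholds) and exon intervals; two constraint
#' tracks (mammalian-PhyloP-like scored over \[-2, 9.28\], primate-
#' PhastCons-like over \[0, 1\]) whose highly constrained elements cover
#' `constrained_frac` (default 3.26%) of the simulated genome; and the
#' syndromic and pleiotropic locus lists, consisting of any planted loci
#' plus random decoy segments.
#'
#' @param cfg a [simConfig()] object.
#' @return list with `genes`, `exons`, `constraint` (list of two scored
#'   `GRanges`), `syndromic`, `pleiotropic`.
#' @export
makeAnnotations <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 1L)
  cl <- cfg$chrom_lengths
  ## genes + exons
  n_genes <- round(cl / 1e6 * cfg$gene_density_per_mb)
  n_genes[n_genes < 1] <- 1
  gch <- rep(names(cl), n_genes)
  glen <- pmax(2000, round(rlnorm(sum(n_genes), log(30000), 1)))
  gs <- 1 + floor(runif(sum(n_genes)) * pmax(1, cl[gch] - glen))
  genes <- GRanges(gch, IRanges(gs, width = glen))
  genes <- sort(genes[end(genes) <= cl[as.character(seqnames(genes))]])
  ng <- length(genes)
  mcols(genes)$gene_id <- sprintf("G%05d", seq_len(ng))
  forced_h <- runif(ng) < cfg$frac_haplo
  mcols(genes)$pHaplo <- ifelse(forced_h, runif(ng, 0.86, 1),
                                runif(ng, 0, 0.86))
  forced_t <- runif(ng) < cfg$frac_triplo
  mcols(genes)$pTriplo <- ifelse(forced_t, runif(ng, 0.94, 1),
                                 runif(ng, 0, 0.94))
  n_ex <- 1L + rpois(ng, 6)
  gi <- rep.int(seq_len(ng), n_ex)
  elen <- pmin(round(runif(length(gi), 80, 400)), width(genes)[gi])
  es <- start(genes)[gi] +
    floor(runif(length(gi)) * pmax(1, width(genes)[gi] - elen))
  exons <- GRanges(seqnames(genes)[gi],
                   IRanges(es, width = elen),
                   gene_id = mcols(genes)$gene_id[gi])
  ## constraint tracks
  track <- function(lo_hi, decoy_range) {
    if (cfg$constrained_frac == 0)
      return(GRanges(cons_score = numeric()))
    segs <- lapply(names(cl), function(ch) {
      target <- cfg$constrained_frac * cl[[ch]]
      n <- ceiling(target / 1000)
      len <- pmax(100, round(rlnorm(n, log(900), 0.6)))
      cum <- cumsum(len)
      len <- len[cum <= target + 1000]
      n <- length(len)
      st <- 1 + floor(runif(n) * pmax(1, cl[[ch]] - len))
      nd <- round(n * 1.5)   # sub-threshold decoy elements
      dlen <- pmax(100, round(rlnorm(nd, log(900), 0.6)))
      ds <- 1 + floor(runif(nd) * pmax(1, cl[[ch]] - dlen))
      data.frame(chrom = ch, start = c(st, ds), len = c(len, dlen),
                 score = c(runif(n, lo_hi[1], lo_hi[2]),
                           runif(nd, decoy_range[1], decoy_range[2])))
    })
    df <- do.call(rbind, segs)
    sort(GRanges(df$chrom, IRanges(df$start, width = df$len),
                 cons_score = df$score))
  }
  constraint <- list(
    phylop = track(c(2.27, 9.28), c(-2, 2.26)),
    phastcons = track(c(0.96, 1), c(0, 0.95)))
  ## locus lists: planted loci first, decoys after
  planted <- .expand_mirrors(cfg$planted_loci)
  decoys <- function(n, min_len, max_len, prefix) {
    len <- round(runif(n, min_len, max_len))
    chrom <- sample(names(cl), n, replace = TRUE, prob = cl / sum(cl))
    st <- 1 + floor(runif(n) * pmax(1, cl[chrom] - len))
    GRanges(chrom, IRanges(st, width = len),
            locus_id = sprintf("%s%03d", prefix, seq_len(n)),
            cnv_type = sample(.VALID_CNV_TYPES, n, TRUE))
  }
  locus_list <- function(n, rule, sided, prefix, min_len, max_len) {
    base <- GRanges()
    if (!is.null(planted) && nrow(planted)) {
      base <- GRanges(planted$chrom,
                      IRanges(planted$start, planted$end),
                      locus_id = sprintf("%s_planted%02d", prefix,
                                         seq_len(nrow(planted))),
                      cnv_type = planted$cnv_type)
    }
    nd <- max(0L, n - length(base))
    out <- suppressWarnings(c(base, decoys(nd, min_len, max_len, prefix)))
    mcols(out)$rule <- rule
    mcols(out)$sided <- sided
    out
  }
  list(genes = genes, exons = exons, constraint = constraint,
       syndromic = locus_list(cfg$n_syndromic, "syndromic_50", "two",
                              "SYN", 2e5, 3e6),
       pleiotropic = locus_list(cfg$n_pleiotropic, "pleiotropic_seg",
                                "one", "PLE", 2e5, 3e6))
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits `calls.cnv` (PLINK CNV), `samples.tsv`, `probes.tsv`,
#' `genes.bed`, `exons.bed`, `phylop.bed`, `phastcons.bed`,
#' `syndromic.bed` and `pleiotropic.bed` under `dir`.
#'
#' @param sim result of [simulateCnvData()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writePlinkCnv(sim$callset, file.path(dir, "calls.cnv"))
  writeSampleTable(sampleTable(sim$callset), file.path(dir, "samples.tsv"))
  writeProbeMap(sim$probes, file.path(dir, "probes.tsv"))
  writeGeneBed(sim$genes, file.path(dir, "genes.bed"))
  writeExonBed(sim$exons, file.path(dir, "exons.bed"))
  writeConstraintBed(sim$constraint$phylop, file.path(dir, "phylop.bed"))
  writeConstraintBed(sim$constraint$phastcons,
                     file.path(dir, "phastcons.bed"))
  writeLocusBed(sim$syndromic, file.path(dir, "syndromic.bed"))
  writeLocusBed(sim$pleiotropic, file.path(dir, "pleiotropic.bed"))
  invisible(dir)
}
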