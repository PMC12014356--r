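smallCfg <- function(...) {
  simConfig(n_cases = 300, n_controls = 200,
            chrom_lengths = c(chr1 = 5e7, chr2 = 4e7),
            n_recurrent_null = 5, n_syndromic = 6, n_pleiotropic = 6,
            ...)
}

test_that("the seed fully determines the simulated study", {
  s1 <- simulateCnvData(smallCfg(seed = 77))
  s2 <- simulateCnvData(smallCfg(seed = 77))
  expect_identical(as.data.frame(cnvCalls(s1$callset)),
                   as.data.frame(cnvCalls(s2$callset)))
  expect_identical(as.data.frame(sampleTable(s1$callset)),
                   as.data.frame(sampleTable(s2$callset)))
  expect_identical(as.data.frame(s1$genes), as.data.frame(s2$genes))
  s3 <- simulateCnvData(smallCfg(seed = 78))
  expect_false(identical(as.data.frame(cnvCalls(s1$callset)),
                         as.data.frame(cnvCalls(s3$callset))))
})

test_that("background CNV counts match the Poisson rates", {
  cfg <- simConfig(n_cases = 6000, n_controls = 4000,
                   chrom_lengths = c(chr1 = 1e8, chr2 = 1e8),
                   n_recurrent_null = 0, n_syndromic = 2,
                   n_pleiotropic = 2, seed = 9)
  sim <- simulateCnvData(cfg)
  rate <- nCalls(sim$callset) / nSamples(sim$callset)
  # Poisson(0.9) + Poisson(0.7): mean 1.6, 3 Monte-Carlo SEs ~ 0.04
  expect_gt(rate, 1.55)
  expect_lt(rate, 1.65)
  tab <- table(mcols(cnvCalls(sim$callset))$cnv_type)
  expect_equal(unname(tab[["DUP"]] / nSamples(sim$callset)), 0.9,
               tolerance = 0.05)
  expect_equal(unname(tab[["DEL"]] / nSamples(sim$callset)), 0.7,
               tolerance = 0.06)
})

test_that("generated call lengths target the reported rare-CNV median", {
  cfg <- simConfig(n_cases = 6000, n_controls = 4000,
                   chrom_lengths = c(chr1 = 2e8), n_recurrent_null = 0,
                   n_syndromic = 2, n_pleiotropic = 2, seed = 10)
  sim <- simulateCnvData(cfg)
  med <- median(width(cnvCalls(sim$callset)))
  expect_equal(med / 1000, 102.8, tolerance = 0.05)
})

test_that("planted risk loci tilt carrier frequency toward cases", {
  planted <- data.frame(chrom = "chr1", start = 2e7, end = 2.01e7,
                        cnv_type = "DEL", carrier_freq_controls = 0.01,
                        odds_ratio = 5, jitter_sd = 3000)
  cfg <- simConfig(n_cases = 4000, n_controls = 4000,
                   chrom_lengths = c(chr1 = 5e7),
                   planted_loci = planted, n_recurrent_null = 0,
                   n_syndromic = 2, n_pleiotropic = 2, seed = 12)
  sim <- simulateCnvData(cfg)
  gr <- cnvCalls(sim$callset)
  smp <- as.data.frame(sampleTable(sim$callset))
  hit <- countOverlaps(gr, GRanges("chr1", IRanges(2e7, 2.01e7))) > 0 &
    mcols(gr)$cnv_type == "DEL" & width(gr) < 5e5
  carriers <- unique(mcols(gr)$sample_id[hit])
  st <- smp$status[smp$sample_id %in% carriers]
  f1 <- 5 * 0.01 / (1 - 0.01 + 5 * 0.01)
  expect_equal(sum(st == 1), 4000 * f1, tolerance = 0.25)
  expect_equal(sum(st == 0), 40, tolerance = 0.35)
  expect_gt(sum(st == 1), sum(st == 0))
})

test_that("mirror partners get the reciprocal odds ratio", {
  planted <- data.frame(chrom = "chr1", start = 2e7, end = 2.01e7,
                        cnv_type = "DEL", carrier_freq_controls = 0.008,
                        odds_ratio = 4, jitter_sd = 3000, mirror = TRUE)
  cfg <- simConfig(n_cases = 5000, n_controls = 5000,
                   chrom_lengths = c(chr1 = 5e7),
                   planted_loci = planted, n_recurrent_null = 0,
                   n_syndromic = 2, n_pleiotropic = 2, seed = 13)
  sim <- simulateCnvData(cfg)
  gr <- cnvCalls(sim$callset)
  smp <- as.data.frame(sampleTable(sim$callset))
  seg <- GRanges("chr1", IRanges(2e7, 2.01e7))
  for (tp in c("DEL", "DUP")) {
    hit <- countOverlaps(gr, seg) > 0 & mcols(gr)$cnv_type == tp &
      width(gr) < 5e5
    carriers <- unique(mcols(gr)$sample_id[hit])
    st <- smp$status[smp$sample_id %in% carriers]
    if (tp == "DEL") expect_gt(sum(st == 1), sum(st == 0))
    else expect_lt(sum(st == 1), sum(st == 0))   # protective partner
  }
})

test_that("same-type overlapping planted loci are rejected", {
  planted <- data.frame(chrom = "chr1", start = c(2e7, 2.005e7),
                        end = c(2.01e7, 2.02e7), cnv_type = "DEL",
                        carrier_freq_controls = 0.005, odds_ratio = 2)
  expect_error(simConfig(chrom_lengths = c(chr1 = 5e7),
                         planted_loci = planted), "overlap")
})

test_that("constraint tracks cover the configured genome fraction", {
  cfg <- smallCfg(seed = 20)
  ann <- makeAnnotations(cfg)
  genome <- sum(cfg$chrom_lengths)
  for (nm in c("phylop", "phastcons")) {
    thr <- if (nm == "phylop") 2.27 else 0.96
    hi <- ann$constraint[[nm]]
    hi <- hi[mcols(hi)$cons_score >= thr]
    frac <- sum(width(GenomicRanges::reduce(hi))) / genome
    expect_gt(frac, 0.028)
    expect_lt(frac, 0.038)
  }
  # zero-constraint config empties the tracks and downstream proportions
  cfg0 <- smallCfg(seed = 21, constrained_frac = 0)
  ann0 <- makeAnnotations(cfg0)
  expect_equal(length(ann0$constraint$phylop), 0L)
  call <- GRanges("chr1", IRanges(1e6, 2e6))
  expect_equal(constrainedProportion(call, ann0$constraint$phylop, 2.27), 0)
})

test_that("dosage-sensitivity score fractions follow the config", {
  cfg <- simConfig(n_cases = 10, n_controls = 10,
                   chrom_lengths = c(chr1 = 2e8, chr2 = 2e8),
                   gene_density_per_mb = 20, n_syndromic = 2,
                   n_pleiotropic = 2, seed = 22)
  ann <- makeAnnotations(cfg)
  expect_equal(mean(mcols(ann$genes)$pHaplo >= 0.86), 0.16,
               tolerance = 0.1)
  expect_equal(mean(mcols(ann$genes)$pTriplo >= 0.94), 0.07,
               tolerance = 0.15)
  expect_true(all(mcols(ann$exons)$gene_id %in%
                  mcols(ann$genes)$gene_id))
})

test_that("simulation files round-trip through the pipeline readers", {
  sim <- simulateCnvData(smallCfg(seed = 30))
  dir <- withr::local_tempdir()
  writeSimulation(sim, dir)
  cs <- readPlinkCnv(file.path(dir, "calls.cnv"),
                     samples = readSampleTable(file.path(dir, "samples.tsv")))
  expect_equal(nCalls(cs), nCalls(sim$callset))
  expect_equal(start(cnvCalls(cs)), start(cnvCalls(sim$callset)))
  probes <- readProbeMap(file.path(dir, "probes.tsv"))
  expect_equal(length(probes), length(sim$probes))
  genes <- readGeneBed(file.path(dir, "genes.bed"))
  expect_equal(length(genes), length(sim$genes))
  expect_equal(mcols(genes)$pHaplo, mcols(sim$genes)$pHaplo,
               tolerance = 1e-6)
  expect_equal(start(genes), start(sim$genes))   # BED offset round-trip
  loci <- readLocusBed(file.path(dir, "syndromic.bed"))
  expect_equal(length(loci), length(sim$syndromic))
  expect_equal(mcols(loci)$rule, mcols(sim$syndromic)$rule)
})
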