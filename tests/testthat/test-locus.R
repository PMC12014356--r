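synLocus <- function(start = 1e6, end = 2.1e6, type = "DEL",
                     rule = "syndromic_50", id = "L1", sided = "two") {
  GRanges("chr1", IRanges(start, end), locus_id = id, cnv_type = type,
          rule = rule, sided = sided)
}

callGr <- function(start, end, type = "DEL") {
  GRanges("chr1", IRanges(start, end), sample_id = "S1",
          cnv_type = type, n_probes = 20L, score = 30)
}

test_that("syndromic rule accepts either 50% denominator", {
  locus <- synLocus(1e6, 1e6 + 1.1e6 - 1)         # 1.1 Mb region
  # 40 kb call fully inside: ov/len(call) = 1 >= 0.5
  expect_true(annotateLocus(callGr(1.2e6, 1.2e6 + 39999), locus))
  # large call covering >=50% of the region, <50% of itself
  big <- callGr(1e6, 1e6 + 5.6e5)                 # covers 51% of region
  expect_true(annotateLocus(GRanges("chr1", IRanges(4e5, 1e6 + 5.6e5),
    sample_id = "S1", cnv_type = "DEL", n_probes = 20L, score = 1), locus))
  # small overlap failing both denominators
  expect_false(annotateLocus(callGr(1e5, 1.2e6), locus))  # ov 0.2Mb
  # wrong CNV type never annotates
  expect_false(annotateLocus(callGr(1.2e6, 1.3e6, "DUP"), locus))
})

test_that("pleiotropic rule applies the 100kb/50% and 25% clauses", {
  seg <- synLocus(1e6, 1.2e6 - 1, rule = "pleiotropic_seg")  # 200 kb
  # 60 kb call overlapping by 55 kb: 55/200 = 0.275 >= 0.25
  expect_true(annotateLocus(callGr(1.2e6 - 55000, 1.2e6 + 4999), seg))
  # 60 kb call overlapping by 45 kb: fails both clauses (below 100 kb)
  expect_false(annotateLocus(callGr(1.2e6 - 45000, 1.2e6 + 14999), seg))
  # 120 kb call with 60 kb overlap: >=100 kb and ov >= 50% of the call
  expect_true(annotateLocus(callGr(1.2e6 - 60000, 1.2e6 + 59999), seg))
  # 120 kb call with 45 kb overlap: 45/120 < 0.5 and 45/200 < 0.25
  expect_false(annotateLocus(callGr(1.2e6 - 45000, 1.2e6 + 74999), seg))
})

test_that("exon rule needs 1 bp of exon overlap; intronic calls fail", {
  locus <- synLocus(1e6, 2e6, rule = "exon_1bp")
  exons <- GRanges("chr1", IRanges(c(1.0e6, 1.5e6), width = 200),
                   gene_id = "L1")
  intronic <- callGr(1.1e6, 1.4e6)        # between the two exons
  expect_false(annotateLocus(intronic, locus, exons))
  touching <- callGr(1.1e6, 1.5e6)        # reaches exon 2 first base
  expect_true(annotateLocus(touching, locus, exons))
  expect_error(annotateLocus(touching, locus), "exon")
})

test_that("a call identical to its locus satisfies all three rules", {
  for (rule in c("syndromic_50", "pleiotropic_seg")) {
    locus <- synLocus(1e6, 1.3e6, rule = rule)
    expect_true(annotateLocus(callGr(1e6, 1.3e6), locus))
  }
  locus <- synLocus(1e6, 1.3e6, rule = "exon_1bp")
  exons <- GRanges("chr1", IRanges(1.1e6, width = 300), gene_id = "L1")
  expect_true(annotateLocus(callGr(1e6, 1.3e6), locus, exons))
})

test_that("locus scan reports unobserved loci and exact Bonferroni flags", {
  set.seed(41)
  n <- 600
  calls <- data.frame(
    sample_id = sprintf("S%03d", 1:24), chrom = "chr1",
    start = 1e6, end = 1.1e6, cnv_type = "DEL")
  status <- rep(c(1L, 0L), each = n / 2)
  cs <- toyCallSet(calls, n_extra_controls = n - 24,
                   status = c(rep(1L, 20), rep(0L, 4),
                              rep(1L, 280), rep(0L, 296)),
                   pc1 = rnorm(n))
  loci <- c(synLocus(1e6, 1.1e6, id = "hit"),
            synLocus(5e6, 5.2e6, id = "empty"))
  res <- locusScan(cs, loci, bonferroni_n = 67)
  expect_equal(res$status, c("tested", "unobserved"))
  expect_equal(res$n_case_carriers[1], 20)
  expect_equal(res$n_control_carriers[1], 4)
  expect_equal(res$bonferroni_alpha, rep(0.05 / 67, 2))
  expect_equal(res$significant,
               !is.na(res$p_sided) & res$p_sided < 0.05 / 67)
  expect_true(res$OR[1] > 1)
})

test_that("one-sided locus lists halve the risk-direction p", {
  calls <- data.frame(
    sample_id = sprintf("S%03d", 1:12), chrom = "chr1",
    start = 1e6, end = 1.25e6, cnv_type = "DUP")
  cs <- toyCallSet(calls, n_extra_controls = 188,
                   status = c(rep(1L, 10), rep(0L, 2),
                              rep(c(1L, 0L), 94)))
  two <- locusScan(cs, synLocus(1e6, 1.25e6, type = "DUP"))
  one <- locusScan(cs, synLocus(1e6, 1.25e6, type = "DUP",
                                rule = "pleiotropic_seg", sided = "one"))
  expect_equal(one$p_sided, two$p_two_sided / 2, tolerance = 1e-9)
})

test_that("carrier status is sample-level, not call-level", {
  calls <- data.frame(
    sample_id = c("S1", "S1", "S2"), chrom = "chr1",
    start = c(1e6, 1.05e6, 1e6), end = c(1.2e6, 1.21e6, 1.2e6),
    cnv_type = "DEL")
  cs <- toyCallSet(calls, n_extra_controls = 3)
  carrier <- locusCarriers(cs, synLocus(1e6, 1.2e6))
  expect_equal(sum(carrier), 2)        # S1 counted once despite 2 calls
})

test_that("BMI linear model recovers a planted carrier effect", {
  set.seed(55)
  n <- 500
  calls <- data.frame(
    sample_id = sprintf("S%03d", 1:40), chrom = "chr1",
    start = 1e6, end = 1.1e6, cnv_type = "DEL")
  cs0 <- toyCallSet(calls, n_extra_controls = n - 40,
                    status = rep(1L, n), pc1 = rnorm(n))
  smp <- as.data.frame(sampleTable(cs0))
  carrier <- smp$sample_id %in% sprintf("S%03d", 1:40)
  smp$bmi_lowest <- rnorm(n, 15.2, 1) - 2 * carrier
  cs <- CnvCallSet(cnvCalls(cs0), smp, "toy")
  res <- bmiLinear(cs, synLocus(1e6, 1.1e6), stratum = "cases")
  expect_equal(res$status, "tested")
  expect_true(res$ci_low < -2 && -2 < res$ci_high)
  expect_true(res$p < 0.01)
  # no carriers in the control stratum -> unobserved
  res0 <- bmiLinear(cs, synLocus(5e6, 6e6), stratum = "cases")
  expect_equal(res0$status, "unobserved")
})

test_that("single-carrier BMI models are flagged low-information", {
  set.seed(56)
  n <- 60
  calls <- data.frame(sample_id = "S001", chrom = "chr1",
                      start = 1e6, end = 1.1e6, cnv_type = "DEL")
  cs0 <- toyCallSet(calls, n_extra_controls = n - 1,
                    status = rep(1L, n))
  smp <- as.data.frame(sampleTable(cs0))
  smp$bmi_lowest <- rnorm(n, 15, 2)
  cs <- CnvCallSet(cnvCalls(cs0), smp, "toy")
  res <- bmiLinear(cs, synLocus(1e6, 1.1e6), stratum = "cases")
  expect_equal(res$status, "low_information")
  expect_true(is.finite(res$slope))
})
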