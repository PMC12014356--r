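bpCallSet <- function(calls, ...) toyCallSet(calls, ...)

test_that("breakpoints are the deduplicated union of call endpoints", {
  calls <- data.frame(
    sample_id = c("S1", "S2", "S3"), chrom = "chr1",
    start = c(100000, 100000, 150000),
    end = c(200000, 200000, 250000),
    cnv_type = c("DEL", "DEL", "DUP"))
  bp <- enumerateBreakpoints(bpCallSet(calls))
  expect_equal(start(bp), c(100000, 150000, 200000, 250000))
  expect_equal(mcols(bp)$origin, c("start", "start", "end", "end"))
  empty <- bpCallSet(calls[0, ], n_extra_controls = 2)
  expect_equal(length(enumerateBreakpoints(empty)), 0L)
})

test_that("encoding follows the dup-only/del-only truth table", {
  calls <- data.frame(
    sample_id = c("A", "B", "C", "C"), chrom = "chr1",
    start = c(100000, 100000, 100000, 120000),
    end = c(200000, 200000, 200000, 180000),
    cnv_type = c("DUP", "DEL", "DUP", "DEL"))
  cs <- bpCallSet(calls, n_extra_controls = 1)   # sample D: no calls
  bm_dup <- encodeBreakpoints(cs, "dup_only")
  bm_del <- encodeBreakpoints(cs, "del_only")
  ids <- bm_dup@sample_id
  p <- which(start(breakpoints(bm_dup)) == 150000)  # no bp there
  expect_equal(length(p), 0L)
  at <- function(bm, sample, pos) {
    i <- match(sample, bm@sample_id)
    j <- which(start(breakpoints(bm)) == pos)
    if (altMatrix(bm)[i, j] == 1) "ALT"
    else if (missingMatrix(bm)[i, j] == 1) "MISSING" else "REF"
  }
  # A: DUP only -> dup ALT, del MISSING
  expect_equal(at(bm_dup, "A", 150000 - 30000), "ALT")
  expect_equal(at(bm_del, "A", 120000), "MISSING")
  # B: DEL only -> reciprocal
  expect_equal(at(bm_dup, "B", 120000), "MISSING")
  expect_equal(at(bm_del, "B", 120000), "ALT")
  # C: both types cover 120000-180000 -> ALT in both models
  expect_equal(at(bm_dup, "C", 150000 - 30000), "ALT")
  expect_equal(at(bm_del, "C", 120000), "ALT")
  # D: no calls -> REF everywhere
  expect_equal(at(bm_dup, "X0001", 120000), "REF")
  expect_equal(at(bm_del, "X0001", 120000), "REF")
  # a call is an observation at both of its own endpoints
  expect_equal(at(bm_del, "C", 120000), "ALT")
  expect_equal(at(bm_del, "C", 180000), "ALT")
})

test_that("models are complementary outside doubly-covered positions", {
  set.seed(61)
  n_calls <- 40
  calls <- data.frame(
    sample_id = sample(sprintf("S%02d", 1:12), n_calls, replace = TRUE),
    chrom = "chr1",
    start = st <- sample(seq(1e5, 2e6, by = 1e4), n_calls),
    end = st + sample(seq(3e4, 3e5, by = 1e4), n_calls, replace = TRUE),
    cnv_type = sample(c("DEL", "DUP"), n_calls, replace = TRUE))
  cs <- bpCallSet(calls)
  bm_dup <- encodeBreakpoints(cs, "dup_only")
  bm_del <- encodeBreakpoints(cs, "del_only")
  gr <- cnvCalls(cs)
  ids <- bm_dup@sample_id
  bp <- breakpoints(bm_dup)
  cov_type <- function(type) {
    g <- gr[mcols(gr)$cnv_type == type]
    h <- findOverlaps(bp, g)
    m <- Matrix::sparseMatrix(
      i = match(mcols(g)$sample_id[subjectHits(h)], ids),
      j = queryHits(h), x = 1, dims = dim(altMatrix(bm_dup)))
    m > 0
  }
  cd <- cov_type("DUP"); cl <- cov_type("DEL")
  ref_both <- altMatrix(bm_dup) + missingMatrix(bm_dup) +
    altMatrix(bm_del) + missingMatrix(bm_del) == 0
  expect_true(all((!cd & !cl) == as.matrix(ref_both)))
  # MISSING in exactly one model iff covered by exactly one type
  mis_one <- xor(as.matrix(missingMatrix(bm_dup) > 0),
                 as.matrix(missingMatrix(bm_del) > 0))
  expect_true(all(mis_one == as.matrix(xor(cd, cl))))
  # ALT iff covered by the model's own type
  expect_true(all(as.matrix(altMatrix(bm_dup) > 0) == as.matrix(cd)))
  expect_true(all(as.matrix(altMatrix(bm_del) > 0) == as.matrix(cl)))
})

test_that("breakpoint frequencies use the non-missing denominator", {
  calls <- data.frame(
    sample_id = c("S1", "S2", "S3"), chrom = "chr1",
    start = c(100000, 100000, 100000),
    end = c(200000, 200000, 150000),
    cnv_type = c("DUP", "DUP", "DEL"))
  cs <- bpCallSet(calls, n_extra_controls = 197)  # 200 samples
  bm <- encodeBreakpoints(cs, "dup_only")
  fr <- breakpointFrequency(bm)
  j <- which(start(breakpoints(bm)) == 100000)
  expect_equal(fr$alt_count[j], 2L)
  expect_equal(fr$n_nonmissing[j], 199L)     # S3 missing (DEL covers)
  expect_equal(fr$freq[j], 2 / 199)
  # rare filter drops zero-ALT and frequent columns
  bmr <- filterRareBreakpoints(bm, max_freq = 0.01)
  expect_true(all(breakpointFrequency(bmr)$alt_count > 0))
  expect_true(all(breakpointFrequency(bmr)$freq < 0.01))
  bmr2 <- filterRareBreakpoints(bm, max_freq = 2 / 199)  # strict bound
  expect_false(100000 %in% start(breakpoints(bmr2)))
})

test_that("r-squared matches the hand-computed Pearson formula", {
  # x = (1,1,0,0,0), y = (1,0,0,0,0): r^2 = 9/24 = 0.375
  calls <- data.frame(
    sample_id = c("S1", "S2", "S1"), chrom = "chr1",
    start = c(100000, 100000, 300000),
    end = c(200000, 200000, 400000),
    cnv_type = "DEL")
  cs <- bpCallSet(calls, n_extra_controls = 3)   # 5 samples
  bm <- encodeBreakpoints(cs, "del_only")
  i <- which(start(breakpoints(bm)) == 120000)   # S1+S2 carry
  j <- which(start(breakpoints(bm)) == 320000)   # S1 carries
  expect_equal(length(c(i, j)), 0L)              # interior, no bp
  i <- which(start(breakpoints(bm)) == 100000)
  j <- which(start(breakpoints(bm)) == 300000)
  expect_equal(ldR2(bm, i, j), 9 / 24)
  expect_equal(ldR2(bm, i, i), 1)
  # constant column on shared support -> 0 with the undefined flag
  cs1 <- bpCallSet(calls[3, , drop = FALSE], n_extra_controls = 0)
  bm1 <- encodeBreakpoints(cs1, "del_only")
  r <- ldR2(bm1, 1, 2)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "undefined"))
})

test_that("scan engines agree and count carriers by status", {
  set.seed(62)
  n <- 800
  carriers <- lapply(1:6, function(i) sample(n, 12))
  calls <- do.call(rbind, lapply(1:6, function(i)
    data.frame(sample_id = sprintf("S%04d", carriers[[i]]),
               chrom = "chr1", start = i * 1e6,
               end = i * 1e6 + 1e5, cnv_type = "DEL")))
  ids <- sprintf("S%04d", 1:n)
  status <- rep(c(1L, 0L), each = n / 2)
  cs <- CnvCallSet(
    GRanges(calls$chrom, IRanges(calls$start, calls$end),
            sample_id = calls$sample_id, cnv_type = calls$cnv_type,
            n_probes = 40L, score = 30),
    data.frame(sample_id = ids, status = status,
               cohort = rep(c("a", "b"), n / 2), pc1 = rnorm(n)), "toy")
  bm <- filterRareBreakpoints(encodeBreakpoints(cs, "del_only"), 0.05)
  sc_off <- scanBreakpoints(bm, sampleTable(cs), engine = "offset")
  sc_joint <- scanBreakpoints(bm, sampleTable(cs), engine = "joint")
  expect_equal(sc_off$beta, sc_joint$beta, tolerance = 0.02)
  expect_equal(sc_off$p_two_sided, sc_joint$p_two_sided,
               tolerance = 0.01)
  j <- which(sc_off$pos == 1e6)
  expect_equal(sc_off$alt_case[j] + sc_off$alt_control[j], 12L)
  expect_equal(sc_off$alt_case[j],
               sum(status[carriers[[1]]] == 1))
  expect_equal(attr(sc_off, "bonferroni_alpha"), 0.05 / nrow(sc_off))
})

test_that("clumping traces the hand-built CNVR and applies all filters", {
  # lead at 1,000,000 shared by 10 case-heavy carriers; a correlated
  # breakpoint at 1,040,000 (same carriers, r^2 = 1); an uncorrelated
  # rare breakpoint at 1,100,000; a far breakpoint at 1,301,001
  n <- 2000
  ids <- sprintf("S%04d", 1:n)
  status <- rep(c(1L, 0L), each = n / 2)
  car <- ids[c(1:9, 1001)]                      # 9 cases, 1 control
  other <- ids[c(500:504, 1500:1504)]           # balanced carriers
  calls <- rbind(
    data.frame(sample_id = car, chrom = "chr1", start = 1000000,
               end = 1040000, cnv_type = "DEL"),
    data.frame(sample_id = other, chrom = "chr1", start = 1100000,
               end = 1150000, cnv_type = "DEL"),
    data.frame(sample_id = car, chrom = "chr1", start = 1301001,
               end = 1350000, cnv_type = "DEL"))
  cs <- CnvCallSet(
    GRanges(calls$chrom, IRanges(calls$start, calls$end),
            sample_id = calls$sample_id, cnv_type = calls$cnv_type,
            n_probes = 25L, score = 30),
    data.frame(sample_id = ids, status = status, cohort = "a",
               pc1 = 0), "toy")
  bm <- encodeBreakpoints(cs, "del_only")
  sc <- scanBreakpoints(bm, sampleTable(cs))
  probes <- toyProbes(to = 2e6, by = 2000)
  cnvr <- clumpCnvrs(sc, bm, cs, probes)
  expect_equal(nrow(cnvr), 2L)   # the far clump is its own CNVR
  lead <- cnvr[cnvr$lead_pos %in% c(1000000, 1040000), ]
  # span covers lead and its r^2 = 1 partner, not the 1,100,000 bp
  # (uncorrelated) nor the 1,301,001 bp (outside the 300 kb window
  # from the lead would still correlate, but it forms its own span)
  expect_equal(lead$start, 1000000)
  expect_equal(lead$end, 1040000)
  expect_equal(lead$length_kb, 40)
  expect_equal(lead$n_probes, 21L)
  expect_equal(lead$n_case_carriers, 9L)
  expect_equal(lead$n_control_carriers, 1L)
  expect_true(lead$OR > 1)
  # probe filter: a sparse probe map suppresses the emission
  cnvr2 <- clumpCnvrs(sc, bm, cs, toyProbes(to = 2e6, by = 5000))
  expect_true(all(cnvr2$n_probes >= 10L))
  expect_false(any(cnvr2$length_kb < 20))
})

test_that("protective leads and short spans are not emitted", {
  n <- 1000
  ids <- sprintf("S%04d", 1:n)
  status <- rep(c(1L, 0L), each = n / 2)
  car <- ids[c(1, 501:511)]                     # 1 case, 11 controls
  calls <- data.frame(sample_id = car, chrom = "chr1",
                      start = 1000000, end = 1040000, cnv_type = "DEL")
  cs <- CnvCallSet(
    GRanges(calls$chrom, IRanges(calls$start, calls$end),
            sample_id = calls$sample_id, cnv_type = calls$cnv_type,
            n_probes = 25L, score = 30),
    data.frame(sample_id = ids, status = status, cohort = "a",
               pc1 = 0), "toy")
  bm <- encodeBreakpoints(cs, "del_only")
  sc <- scanBreakpoints(bm, sampleTable(cs))
  expect_true(any(sc$p_two_sided <= 0.05 & sc$beta < 0))
  cnvr <- clumpCnvrs(sc, bm, cs, toyProbes())
  expect_equal(nrow(cnvr), 0L)                  # OR < 1: no risk CNVR
})

test_that("mirror scan flags opposite nominal signals within the window", {
  dup <- data.frame(chrom = "chr5", pos = 1000000, model = "dup_only",
                    beta = log(0.5), OR = 0.5, p_two_sided = 0.03)
  del <- data.frame(chrom = "chr5", pos = 1040000, model = "del_only",
                    beta = log(2), OR = 2, p_two_sided = 0.04)
  expect_equal(nrow(mirrorScan(dup, del)), 1L)
  del_far <- transform(del, pos = 1400001)
  expect_equal(nrow(mirrorScan(dup, del_far)), 0L)
  dup_same <- transform(dup, beta = log(2), OR = 2)
  expect_equal(nrow(mirrorScan(dup_same, del)), 0L)
  dup_weak <- transform(dup, p_two_sided = 0.06)
  expect_equal(nrow(mirrorScan(dup_weak, del)), 0L)
})
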