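#' @importFrom IRanges subsetByOverlaps countOverlaps reduce
#' @importFrom GenomicRanges findOverlaps GRangesList
#' @importFrom stats confint
NULL

.DOSAGE_THRESHOLDS <- c(pHaplo = 0.86, pTriplo = 0.94)
.CONSTRAINT_THRESHOLDS <- c(phylop = 2.27, phastcons = 0.96)

#' Per-CNV proportion of highly constrained bases
#'
#' Fraction of a call's bases lying in constraint-track intervals whose
#' score is at or above `threshold`; "highly constrained" defaults follow
#' the tracks in use (mammalian PhyloP >= 2.27, primate PhastCons >=
#' 0.96, each flagging about 3.26% of the genome). Intervals are merged
#' before counting so overlapping elements are not double-counted.
#'
#' @param calls `GRanges` of CNV calls.
#' @param track constraint `GRanges`, optionally with a `cons_score`
#'   metadata column (absent: every interval counts as constrained).
#' @param threshold score cutoff applied to `cons_score`.
#' @return numeric vector of fractions in `[0, 1]`, one per call.
#' @export
constrainedProportion <- function(calls, track, threshold = NULL) {
  if (!is.null(threshold) && "cons_score" %in% names(mcols(track)))
    track <- track[mcols(track)$cons_score >= threshold]
  track <- reduce(track)
  out <- numeric(length(calls))
  hits <- findOverlaps(calls, track)
  if (length(hits)) {
    ov <- pmin(end(calls)[queryHits(hits)], end(track)[subjectHits(hits)]) -
      pmax(start(calls)[queryHits(hits)], start(track)[subjectHits(hits)]) + 1
    agg <- tapply(ov, queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out / width(calls)
}

#' Genome-wide per-sample rCNV burden profiles
#'
#' Computes the five burden metrics per sample from a QC'd,
#' rarity-filtered call set: `total_kb` (summed CNV length), `n_cnv`
#' (call count), `n_haplo_del_genes` (distinct haploinsufficient genes,
#' `pHaplo >= 0.86`, intersected by at least 1 bp by a deletion),
#' `n_triplo_dup_genes` (distinct triplosensitive genes, `pTriplo >=
#' 0.94`, intersected by a duplication), and the average per-CNV
#' proportion of highly constrained bases for the mammalian
#' (`mean_constrained_prop_mam`) and primate
#' (`mean_constrained_prop_pri`) tracks. Genes are counted once per
#' sample per metric however many CNVs hit them. Samples with no CNVs get
#' zero counts and zero constrained proportions and are retained.
#'
#' @param x a [CnvCallSet-class] (already QC'd and rarity-filtered).
#' @param genes gene `GRanges` with `gene_id`, `pHaplo`, `pTriplo`
#'   metadata columns, or `NULL` to omit the gene metrics.
#' @param constraint named list with elements `phylop` and/or
#'   `phastcons`, each a constraint `GRanges` (see
#'   [constrainedProportion()]); missing tracks omit the corresponding
#'   metric with a warning rather than zero-filling it.
#' @param phaplo,ptriplo,phylop,phastcons thresholds for the
#'   dosage-sensitivity scores and constraint tracks.
#' @return `data.frame`, one row per sample (all samples in
#'   `sampleTable(x)`), with `sample_id` and the metric columns present
#'   given the supplied annotations.
#' @export
burdenProfiles <- function(x, genes = NULL, constraint = NULL,
                           phaplo = 0.86, ptriplo = 0.94,
                           phylop = 2.27, phastcons = 0.96) {
  gr <- cnvCalls(x)
  ids <- sampleTable(x)$sample_id
  si <- match(mcols(gr)$sample_id, ids)
  prof <- data.frame(sample_id = ids,
                     total_kb = 0, n_cnv = 0L,
                     stringsAsFactors = FALSE)
  if (length(gr)) {
    kb <- tapply(width(gr) / 1000, si, sum)
    cnt <- tabulate(si, nbins = length(ids))
    prof$total_kb[as.integer(names(kb))] <- as.numeric(kb)
    prof$n_cnv <- cnt
  }
  if (!is.null(genes)) {
    count_gene_hits <- function(type, score_col, thr) {
      gset <- genes[mcols(genes)[[score_col]] >= thr]
      calls <- gr[mcols(gr)$cnv_type == type]
      out <- integer(length(ids))
      h <- findOverlaps(calls, gset, minoverlap = 1L)
      if (length(h)) {
        samp <- si[mcols(gr)$cnv_type == type][queryHits(h)]
        key <- paste0(samp, "\r", subjectHits(h))
        u <- !duplicated(key)
        agg <- table(samp[u])
        out[as.integer(names(agg))] <- as.integer(agg)
      }
      out
    }
    prof$n_haplo_del_genes <- count_gene_hits("DEL", "pHaplo", phaplo)
    prof$n_triplo_dup_genes <- count_gene_hits("DUP", "pTriplo", ptriplo)
  } else {
    warning("no gene annotations supplied; dosage-sensitive gene metrics omitted")
  }
  mean_prop <- function(track, thr) {
    pp <- constrainedProportion(gr, track, threshold = thr)
    out <- numeric(length(ids))
    if (length(gr)) {
      agg <- tapply(pp, si, mean)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
    out
  }
  if (!is.null(constraint$phylop))
    prof$mean_constrained_prop_mam <- mean_prop(constraint$phylop, phylop)
  else warning("no PhyloP track supplied; mammalian constraint metric omitted")
  if (!is.null(constraint$phastcons))
    prof$mean_constrained_prop_pri <- mean_prop(constraint$phastcons,
                                                phastcons)
  else warning("no PhastCons track supplied; primate constraint metric omitted")
  prof
}

#' Covariate-adjusted logistic burden test of one metric
#'
#' Ordinary maximum-likelihood logistic regression of case-control status
#' on a per-sample burden metric (scaled, e.g. per 100 kb of total
#' distance) plus cohort and ancestry-PC covariates. Burden metrics are
#' not rare events at the sample level, so plain ML is used; if the fit
#' separates, the Firth engine takes over and the result is flagged. A
#' metric constant across samples is degenerate and returned untested.
#'
#' @param profiles output of [burdenProfiles()].
#' @param samples sample table with `status` and covariates.
#' @param metric metric column name in `profiles`.
#' @param scale unit divisor (e.g. `100` to report the `total_kb` odds
#'   ratio per 100 kb).
#' @param covariates covariate columns (default cohort + pc1).
#' @param sided sidedness of the reported `p_sided` (`"one"` = risk
#'   direction, the convention for burden hypotheses).
#' @return one-row `data.frame`: `metric`, `scale`, `OR`, `ci_low`,
#'   `ci_high`, `p_two_sided`, `p_one_sided`, `p_sided`, `engine`,
#'   `status`.
#' @export
burdenTest <- function(profiles, samples, metric, scale = 1,
                       covariates = c("cohort", "pc1"),
                       sided = c("one", "two")) {
  sided <- match.arg(sided)
  df <- as.data.frame(samples)
  stopifnot(nrow(profiles) == nrow(df),
            all(profiles$sample_id == df$sample_id))
  v <- profiles[[metric]] / scale
  out <- data.frame(metric = metric, scale = scale, OR = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_two_sided = NA_real_, p_one_sided = NA_real_,
                    p_sided = NA_real_, engine = NA_character_,
                    status = "degenerate", stringsAsFactors = FALSE)
  if (length(unique(v)) < 2L) return(out)
  X <- cbind(.assoc_design(df, covariates),
             matrix(v, ncol = 1, dimnames = list(NULL, "burden")))
  fit <- suppressWarnings(glm.fit(X, df$status, family = binomial()))
  separated <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8) ||
    abs(coef(fit)["burden"]) > 15
  if (!separated) {
    b <- coef(fit)["burden"]
    se <- sqrt(diag(chol2inv(fit$qr$qr[seq_len(ncol(X)),
                                       seq_len(ncol(X))])))[ncol(X)]
    z <- b / se
    p2 <- 2 * pnorm(-abs(z))
    out$OR <- exp(b)
    out$ci_low <- exp(b - qnorm(0.975) * se)
    out$ci_high <- exp(b + qnorm(0.975) * se)
    out$p_two_sided <- p2
    out$p_one_sided <- if (b > 0) p2 / 2 else 1 - p2 / 2
    out$engine <- "ml"
  } else {
    ff <- firthFit(X, df$status, terms = "burden", ci = "profile")
    out$OR <- exp(unname(ff$coefficients["burden"]))
    out$ci_low <- exp(unname(ff$ci_low["burden"]))
    out$ci_high <- exp(unname(ff$ci_high["burden"]))
    out$p_two_sided <- unname(ff$p_two_sided["burden"])
    out$p_one_sided <- unname(ff$p_one_sided["burden"])
    out$engine <- "firth"
  }
  out$p_sided <- if (sided == "two") out$p_two_sided else out$p_one_sided
  out$status <- "tested"
  out
}

#' Run the standard five-metric burden panel
#'
#' Convenience wrapper running [burdenTest()] for each metric present in
#' the profiles, with total distance scaled per 100 kb.
#' @inheritParams burdenTest
#' @return `data.frame` with one row per metric.
#' @export
burdenPanel <- function(profiles, samples, covariates = c("cohort", "pc1"),
                        sided = c("one", "two")) {
  sided <- match.arg(sided)
  metrics <- setdiff(colnames(profiles), "sample_id")
  scales <- ifelse(metrics == "total_kb", 100, 1)
  do.call(rbind, Map(function(m, s)
    burdenTest(profiles, samples, m, scale = s,
               covariates = covariates, sided = sided),
    metrics, scales))
}

.LENGTH_BINS_KB <- c(0, 100, 200, 500, Inf)
.LENGTH_LABELS <- c("20-100kb", "100-200kb", "200-500kb", ">500kb")
.FREQ_BREAKS <- c(1, 2, 6, 21, Inf)
.FREQ_LABELS <- c("singleton", "2-5", "6-20", ">20")

#' Stratified (partitioned) burden tests
#'
#' Partitions the call set by CNV type, length bin (left-closed,
#' right-open; defaults 20-100, 100-200, 200-500, >500 kb) or carrier
#' count bin (singletons upward to the 1% cap), recomputes the per-sample
#' CNV count within each stratum, and runs one covariate-adjusted burden
#' test per stratum. Strata partition the calls, so per-sample stratified
#' counts sum to the unstratified `n_cnv`. Empty strata are reported with
#' `status = "unobserved"`.
#'
#' @param x a QC'd, rarity-filtered [CnvCallSet-class].
#' @param by `"type"`, `"length"` (crossed with type) or `"frequency"`.
#' @param length_bins_kb,freq_breaks bin edges (left-closed).
#' @param covariates,sided passed to [burdenTest()].
#' @return `data.frame` of burden results with `stratum` (and where
#'   applicable `cnv_type`) columns.
#' @export
partitionBurden <- function(x, by = c("type", "length", "frequency"),
                            length_bins_kb = .LENGTH_BINS_KB,
                            freq_breaks = .FREQ_BREAKS,
                            covariates = c("cohort", "pc1"),
                            sided = c("one", "two")) {
  by <- match.arg(by)
  sided <- match.arg(sided)
  gr <- cnvCalls(x)
  df <- as.data.frame(sampleTable(x))
  ids <- df$sample_id
  si <- match(mcols(gr)$sample_id, ids)
  strata <- switch(by,
    type = data.frame(stratum = mcols(gr)$cnv_type,
                      cnv_type = mcols(gr)$cnv_type),
    length = {
      lab <- if (length(length_bins_kb) - 1L == length(.LENGTH_LABELS) &&
                 all(length_bins_kb == .LENGTH_BINS_KB)) .LENGTH_LABELS
             else NULL
      bin <- cut(width(gr) / 1000, breaks = length_bins_kb,
                 labels = lab, right = FALSE, include.lowest = TRUE)
      data.frame(stratum = paste(mcols(gr)$cnv_type, bin),
                 cnv_type = mcols(gr)$cnv_type)
    },
    frequency = {
      cnt <- cnvFrequency(x)$count
      bin <- cut(cnt, breaks = freq_breaks,
                 labels = if (all(freq_breaks == .FREQ_BREAKS))
                   .FREQ_LABELS else NULL,
                 right = FALSE, include.lowest = TRUE)
      data.frame(stratum = as.character(bin),
                 cnv_type = mcols(gr)$cnv_type)
    })
  levs <- if (by == "type") .VALID_CNV_TYPES else
    sort(unique(strata$stratum))
  out <- lapply(levs, function(sl) {
    sel <- which(strata$stratum == sl)
    cnt <- tabulate(si[sel], nbins = length(ids))
    prof <- data.frame(sample_id = ids, n_cnv = cnt,
                       stringsAsFactors = FALSE)
    if (!length(sel)) {
      res <- data.frame(metric = "n_cnv", scale = 1, OR = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_two_sided = NA_real_, p_one_sided = NA_real_,
                        p_sided = NA_real_, engine = NA_character_,
                        status = "unobserved", stringsAsFactors = FALSE)
    } else {
      res <- burdenTest(prof, df, "n_cnv", covariates = covariates,
                        sided = sided)
    }
    res$stratum <- sl
    res$n_calls <- length(sel)
    res
  })
  do.call(rbind, out)
}

#' Per-sample stratified counts (partition bookkeeping)
#'
#' Returns the samples-by-strata count matrix underlying
#' [partitionBurden()]; row sums equal the unstratified per-sample CNV
#' count.
#' @inheritParams partitionBurden
#' @return integer matrix, samples x strata.
#' @export
stratifiedCounts <- function(x, by = c("type", "length", "frequency"),
                             length_bins_kb = .LENGTH_BINS_KB,
                             freq_breaks = .FREQ_BREAKS) {
  by <- match.arg(by)
  gr <- cnvCalls(x)
  ids <- sampleTable(x)$sample_id
  si <- match(mcols(gr)$sample_id, ids)
  lab <- switch(by,
    type = mcols(gr)$cnv_type,
    length = paste(mcols(gr)$cnv_type,
                   cut(width(gr) / 1000, breaks = length_bins_kb,
                       right = FALSE, include.lowest = TRUE)),
    frequency = as.character(cut(cnvFrequency(x)$count,
                                 breaks = freq_breaks, right = FALSE,
                                 include.lowest = TRUE)))
  levs <- sort(unique(lab))
  m <- matrix(0L, length(ids), length(levs),
              dimnames = list(ids, levs))
  for (j in seq_along(levs)) {
    cnt <- tabulate(si[lab == levs[j]], nbins = length(ids))
    m[, j] <- cnt
  }
  m
}
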