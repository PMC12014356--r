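#' Annotate CNV calls to a candidate locus
#'
#' Implements the three locus-annotation rules used for the curated CNV
#' lists; a call of the wrong CNV type never annotates, whatever the
#' overlap. With `ov` the call-locus overlap in bp:
#' \describe{
#' \item{`syndromic_50`}{`ov/len(locus) >= 0.5` OR `ov/len(call) >= 0.5`
#'   — the rule for syndromic/developmental regions, covering both
#'   denominators of the 50% criterion.}
#' \item{`pleiotropic_seg`}{(`len(call) >= 100 kb` AND
#'   `ov >= 0.5*len(call)`) OR `ov >= 0.25*len(locus)` — the rule for
#'   pleiotropic dosage-sensitive segments.}
#' \item{`exon_1bp`}{the call overlaps any of the locus's exon intervals
#'   by at least 1 bp — the rule used for exonic NRXN1-style loci, under
#'   which purely intronic calls do not annotate.}
#' }
#'
#' @param calls `GRanges` of CNV calls with `cnv_type`.
#' @param locus length-1 `GRanges` with metadata `locus_id`, `cnv_type`
#'   and `rule` (one of the three rule names).
#' @param exons exon `GRanges` for the locus (required for `exon_1bp`).
#' @return logical vector, one entry per call.
#' @export
annotateLocus <- function(calls, locus, exons = NULL) {
  stopifnot(length(locus) == 1L)
  rule <- mcols(locus)$rule
  out <- logical(length(calls))
  if (!length(calls)) return(out)
  ok_type <- mcols(calls)$cnv_type == mcols(locus)$cnv_type
  same_chr <- as.character(seqnames(calls)) ==
    as.character(seqnames(locus))
  cand <- which(ok_type & same_chr)
  if (!length(cand)) return(out)
  cc <- calls[cand]
  if (rule == "exon_1bp") {
    if (is.null(exons)) stop("rule 'exon_1bp' requires exon intervals")
    out[cand] <- countOverlaps(cc, exons, minoverlap = 1L) > 0
    return(out)
  }
  ov <- pmax(0, pmin(end(cc), end(locus)) - pmax(start(cc), start(locus)) + 1)
  out[cand] <- switch(rule,
    syndromic_50 = ov / width(locus) >= 0.5 | ov / width(cc) >= 0.5,
    pleiotropic_seg = (width(cc) >= 1e5 & ov >= 0.5 * width(cc)) |
      ov >= 0.25 * width(locus),
    stop("unknown annotation rule: ", rule))
  out
}

#' Sample-level carrier indicator for a locus
#'
#' A sample carries a locus if at least one of its calls annotates to it
#' under the locus's rule; the count of annotated calls is irrelevant.
#' @inheritParams annotateLocus
#' @param x a [CnvCallSet-class].
#' @return integer 0/1 vector aligned with `sampleTable(x)`.
#' @export
locusCarriers <- function(x, locus, exons = NULL) {
  ann <- annotateLocus(cnvCalls(x), locus, exons)
  ids <- sampleTable(x)$sample_id
  as.integer(ids %in% mcols(cnvCalls(x))$sample_id[ann])
}

#' Firth association scan over a locus list
#'
#' For each locus, builds the sample-level carrier indicator and runs the
#' covariate-adjusted Firth test of case-control status. Loci with zero
#' carriers are reported as `unobserved` and not tested. The reported
#' `p_sided` follows each locus's `sided` metadata (`"two"` for the
#' syndromic list, where effect direction can be trait-dependent; `"one"`
#' in the risk direction for the pleiotropic disease-risk list). The
#' Bonferroni level is `0.05 / n` with `n` the full list length
#' (unobserved loci included), and `significant` is exactly
#' `p_sided < 0.05/n`.
#'
#' @param x a QC'd, rarity-filtered [CnvCallSet-class].
#' @param loci locus `GRanges` with `locus_id`, `cnv_type`, `rule`,
#'   `sided` metadata.
#' @param exons exon `GRanges` with a `gene_id`/`locus_id`-matching
#'   metadata column `gene_id`, used by `exon_1bp` loci.
#' @param covariates covariates for [firthTest()].
#' @param bonferroni_n Bonferroni denominator; defaults to
#'   `length(loci)`.
#' @param alpha family-wise level (default 0.05).
#' @param ci CI method for the per-locus fits.
#' @return `data.frame`, one row per locus, with carrier counts, OR, CI,
#'   `p_sided`, `bonferroni_alpha`, `significant` and `status`.
#' @export
locusScan <- function(x, loci, exons = NULL,
                      covariates = c("cohort", "pc1"),
                      bonferroni_n = length(loci), alpha = 0.05,
                      ci = "profile") {
  stopifnot(length(loci) > 0L)
  smp <- sampleTable(x)
  res <- lapply(seq_along(loci), function(i) {
    locus <- loci[i]
    ex <- NULL
    if (mcols(locus)$rule == "exon_1bp" && !is.null(exons))
      ex <- exons[mcols(exons)$gene_id == mcols(locus)$locus_id]
    carrier <- locusCarriers(x, locus, ex)
    sided <- if (identical(mcols(locus)$sided, "one")) "one" else "two"
    r <- firthTest(carrier, smp, covariates, sided = sided, ci = ci)
    cbind(data.frame(locus_id = mcols(locus)$locus_id,
                     chrom = as.character(seqnames(locus)),
                     start = start(locus), end = end(locus),
                     cnv_type = mcols(locus)$cnv_type,
                     rule = mcols(locus)$rule, sided = sided,
                     stringsAsFactors = FALSE), r)
  })
  res <- do.call(rbind, res)
  res$bonferroni_alpha <- alpha / bonferroni_n
  res$significant <- !is.na(res$p_sided) & res$p_sided < res$bonferroni_alpha
  res
}

#' Within-stratum linear models of lowest BMI on locus carriership
#'
#' Ordinary least squares `bmi_lowest ~ carrier + cohort + pc1` fitted
#' within cases or within controls separately, one model per locus. Loci
#' with zero carriers in the stratum are `unobserved`; loci with fewer
#' than two carriers are still reported but flagged `low_information`.
#'
#' @inheritParams locusScan
#' @param stratum `"cases"` or `"controls"`.
#' @return `data.frame` with per-locus `slope` (kg/m^2), 95% `ci_low`/
#'   `ci_high`, `p`, carrier count and `status`.
#' @export
bmiLinear <- function(x, loci, exons = NULL,
                      stratum = c("cases", "controls"),
                      covariates = c("cohort", "pc1")) {
  stratum <- match.arg(stratum)
  smp <- as.data.frame(sampleTable(x))
  if (!"bmi_lowest" %in% colnames(smp))
    stop("sample table has no bmi_lowest column")
  keep <- smp$status == (if (stratum == "cases") 1L else 0L) &
    !is.na(smp$bmi_lowest)
  res <- lapply(seq_along(loci), function(i) {
    locus <- loci[i]
    ex <- NULL
    if (mcols(locus)$rule == "exon_1bp" && !is.null(exons))
      ex <- exons[mcols(exons)$gene_id == mcols(locus)$locus_id]
    carrier <- locusCarriers(x, locus, ex)[keep]
    base <- data.frame(locus_id = mcols(locus)$locus_id,
                       stratum = stratum, n_carriers = sum(carrier),
                       slope = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, p = NA_real_,
                       status = "unobserved", stringsAsFactors = FALSE)
    if (sum(carrier) == 0L) return(base)
    df <- smp[keep, , drop = FALSE]
    df$carrier <- carrier
    cv <- intersect(covariates, colnames(df))
    cv <- cv[vapply(cv, function(v) length(unique(df[[v]])) > 1L, TRUE)]
    form <- stats::reformulate(c("carrier", cv), response = "bmi_lowest")
    fit <- stats::lm(form, data = df)
    sm <- summary(fit)$coefficients
    if (!"carrier" %in% rownames(sm)) return(base)
    ci <- stats::confint(fit, "carrier")
    base$slope <- sm["carrier", "Estimate"]
    base$ci_low <- ci[1]; base$ci_high <- ci[2]
    base$p <- sm["carrier", "Pr(>|t|)"]
    base$status <- if (sum(carrier) < 2L) "low_information" else "tested"
    base
  })
  do.call(rbind, res)
}
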