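#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
NULL

.VALID_CNV_TYPES <- c("DEL", "DUP")

#' CnvCallSet: a set of CNV calls with their sample table
#'
#' Container for post-calling copy-number-variant (CNV) calls from a
#' case-control genotyping-array study. Calls are held as a
#' [GenomicRanges::GRanges] (1-based, closed intervals) with metadata columns
#' `sample_id`, `cnv_type` (`"DEL"`/`"DUP"`), `n_probes` and `score`; the
#' sample table is a [S4Vectors::DataFrame] keyed by `sample_id` carrying
#' case/control `status` (1/0), `sex`, `cohort`, ancestry `pc1` and optional
#' `bmi_lowest`/`age` covariates.
#'
#' @slot calls `GRanges` of CNV calls with the metadata columns above.
#' @slot samples `DataFrame` with one row per sample.
#' @slot genome single string, genome build tag (e.g. `"hg38"`).
#'
#' @seealso [CnvCallSet()] for the constructor, [readPlinkCnv()] for I/O.
#' @export
setClass("CnvCallSet",
         representation(calls = "GRanges", samples = "DataFrame",
                        genome = "character"))

setValidity("CnvCallSet", function(object) {
  msg <- character()
  need <- c("sample_id", "cnv_type", "n_probes")
  have <- names(mcols(object@calls))
  if (!all(need %in% have))
    msg <- c(msg, paste("calls must carry metadata columns:",
                        paste(setdiff(need, have), collapse = ", ")))
  else {
    if (!all(mcols(object@calls)$cnv_type %in% .VALID_CNV_TYPES))
      msg <- c(msg, "cnv_type must be 'DEL' or 'DUP'")
    if (any(mcols(object@calls)$n_probes < 1))
      msg <- c(msg, "n_probes must be positive")
    if (any(width(object@calls) < 1))
      msg <- c(msg, "zero-length calls are not allowed")
    if (!"sample_id" %in% colnames(object@samples))
      msg <- c(msg, "sample table must have a sample_id column")
    else {
      if (anyDuplicated(object@samples$sample_id))
        msg <- c(msg, "duplicated sample_id in sample table")
      orphan <- setdiff(mcols(object@calls)$sample_id,
                        object@samples$sample_id)
      if (length(orphan))
        msg <- c(msg, paste0(length(orphan),
                             " call sample_id(s) missing from sample table"))
    }
    st <- object@samples$status
    if (!is.null(st) && !all(is.na(st) | st %in% c(0L, 1L)))
      msg <- c(msg, "status must be 0 (control) or 1 (case)")
  }
  if (length(object@genome) != 1L)
    msg <- c(msg, "genome must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a CnvCallSet
#'
#' @param calls `GRanges` with metadata columns `sample_id`, `cnv_type`
#'   (`"DEL"`/`"DUP"`), `n_probes` and optionally `score`.
#' @param samples `data.frame` or `DataFrame` with a `sample_id` column and
#'   (for association work) `status`, `cohort`, `pc1`.
#' @param genome genome build tag.
#' @return A [CnvCallSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 1.2e6),
#'         sample_id = "S1", cnv_type = "DEL", n_probes = 25L, score = 30)
#' smp <- data.frame(sample_id = "S1", status = 1L, sex = "F",
#'                   cohort = "A", pc1 = 0)
#' CnvCallSet(gr, smp)
#' @export
CnvCallSet <- function(calls, samples, genome = "hg38") {
  if (is.data.frame(samples)) samples <- DataFrame(samples)
  if (!"score" %in% names(mcols(calls))) mcols(calls)$score <- NA_real_
  mcols(calls)$n_probes <- as.integer(mcols(calls)$n_probes)
  new("CnvCallSet", calls = calls, samples = samples, genome = genome)
}

setMethod("show", "CnvCallSet", function(object) {
  tab <- table(factor(mcols(object@calls)$cnv_type, .VALID_CNV_TYPES))
  ncase <- if ("status" %in% colnames(object@samples))
    sum(object@samples$status == 1L) else NA_integer_
  cat("CnvCallSet (", object@genome, "): ",
      length(object@calls), " calls (", tab[["DEL"]], " DEL, ",
      tab[["DUP"]], " DUP) in ", nrow(object@samples), " samples",
      if (!is.na(ncase)) paste0(" (", ncase, " cases)"), "\n", sep = "")
})

#' BreakpointMatrix: sparse sample-by-breakpoint pseudo-genotypes
#'
#' Samples-by-breakpoints encoding of CNV carriership under a single-type
#' model, the genotype-like representation used by the rare-CNV-breakpoint
#' genome-wide scan. Under the duplication-only model a sample is ALT at a
#' breakpoint if a duplication covers the position, MISSING if only a
#' deletion covers it, and REF (copy-neutral) otherwise; the deletion-only
#' model uses the reciprocal encoding. Extra dosage (more than one copy
#' gained/lost) is not distinguished. Stored as two sparse indicator
#' matrices (`Matrix::dgCMatrix`): `alt` and `missing`.
#'
#' @slot alt sparse 0/1 matrix, samples x breakpoints, 1 = ALT.
#' @slot missing sparse 0/1 matrix, 1 = MISSING (opposite-type CNV only).
#' @slot breakpoints `GRanges` of width-1 breakpoint positions with metadata
#'   column `origin` (`"start"`/`"end"`).
#' @slot model `"dup_only"` or `"del_only"`.
#' @slot sample_id character vector of row names.
#' @seealso [encodeBreakpoints()]
#' @export
setClass("BreakpointMatrix",
         representation(alt = "dgCMatrix", missing = "dgCMatrix",
                        breakpoints = "GRanges", model = "character",
                        sample_id = "character"))

setValidity("BreakpointMatrix", function(object) {
  msg <- character()
  if (!object@model %in% c("dup_only", "del_only"))
    msg <- c(msg, "model must be 'dup_only' or 'del_only'")
  if (!identical(dim(object@alt), dim(object@missing)))
    msg <- c(msg, "alt and missing dimensions differ")
  if (nrow(object@alt) != length(object@sample_id))
    msg <- c(msg, "row count must match sample_id length")
  if (ncol(object@alt) != length(object@breakpoints))
    msg <- c(msg, "column count must match breakpoint count")
  if (length(object@alt@x) && any(object@alt@x != 1))
    msg <- c(msg, "alt entries must be 0/1")
  # a cell cannot be both ALT and MISSING
  if (length(object@alt@x) && length(object@missing@x)) {
    both <- object@alt * object@missing
    if (any(both@x != 0)) msg <- c(msg, "cell flagged both ALT and MISSING")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "BreakpointMatrix", function(object) {
  cat("BreakpointMatrix [", object@model, "]: ",
      nrow(object@alt), " samples x ", ncol(object@alt), " breakpoints; ",
      sum(object@alt), " ALT, ", sum(object@missing), " MISSING entries\n",
      sep = "")
})
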