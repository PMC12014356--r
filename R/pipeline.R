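#' Read a pipeline run configuration from YAML
#'
#' The config either carries a `simulate:` block (fields of
#' [simConfig()], including an optional `planted_loci` list of records)
#' or an `inputs:` block with file paths (`calls`, `samples`, `probes`,
#' `genes`, `exons`, `phylop`, `phastcons`, `syndromic`, `pleiotropic`).
#' A `thresholds:` block may override the analysis defaults
#' (`qc_min_length`, `qc_min_probes`, `max_freq`, `r2_min`, `window`,
#' `cnvr_min_length`, `cnvr_min_probes`); unset thresholds keep the
#' study defaults (20 kb, 10 probes, 1%, 0.5, 300 kb, 20 kb, 10).
#'
#' @param path YAML file.
#' @return list with class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "RunConfig")
}

.default_thresholds <- function(overrides = NULL) {
  th <- list(qc_min_length = 20000, qc_min_probes = 10L,
             max_freq = 0.01, ro_threshold = 0.5,
             p_lead = 0.05, r2_min = 0.5, window = 3e5,
             cnvr_min_length = 20000, cnvr_min_probes = 10L,
             mirror_window = 3e5)
  if (!is.null(overrides)) th[names(overrides)] <- overrides
  th
}

.load_inputs <- function(inp) {
  samples <- readSampleTable(inp$samples)
  list(callset = readPlinkCnv(inp$calls, samples = samples),
       probes = readProbeMap(inp$probes),
       genes = if (!is.null(inp$genes)) readGeneBed(inp$genes),
       exons = if (!is.null(inp$exons)) readExonBed(inp$exons),
       constraint = list(
         phylop = if (!is.null(inp$phylop)) readConstraintBed(inp$phylop),
         phastcons = if (!is.null(inp$phastcons))
           readConstraintBed(inp$phastcons)),
       syndromic = if (!is.null(inp$syndromic)) readLocusBed(inp$syndromic),
       pleiotropic = if (!is.null(inp$pleiotropic))
         readLocusBed(inp$pleiotropic))
}

.tsv <- function(df, dir, name) {
  write.table(df, file.path(dir, name), quote = FALSE, sep = "\t",
              row.names = FALSE)
}

#' Run the complete rare-CNV association pipeline
#'
#' Executes QC filtering, rarity filtering, the five-metric burden panel
#' with type/length/frequency partitioning, the syndromic and
#' pleiotropic locus scans (plus BMI models when `bmi_lowest` is
#' present), the duplication-only and deletion-only breakpoint scans
#' with CNVR clumping and mirror detection, and the analytic power
#' table, writing every result table (TSV), the CNVR BED, a filter-stage
#' log and the effective configuration under `out_dir`. Any stage
#' failure aborts with the stage name.
#'
#' @param data either a `RunConfig` (see [readRunConfig()]) or the list
#'   returned by [simulateCnvData()].
#' @param out_dir output directory.
#' @param seed seed used when the config requests simulation.
#' @return invisibly, a list with all in-memory results.
#' @export
runPipeline <- function(data, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- .default_thresholds()
  if (inherits(data, "RunConfig")) {
    th <- .default_thresholds(data$thresholds)
    if (!is.null(data$simulate)) {
      sa <- data$simulate
      if (!is.null(sa$chrom_lengths))
        sa$chrom_lengths <- unlist(sa$chrom_lengths)
      if (!is.null(sa$planted_loci))
        sa$planted_loci <- do.call(rbind,
          lapply(sa$planted_loci, as.data.frame))
      if (is.null(sa$seed)) sa$seed <- seed
      data <- simulateCnvData(do.call(simConfig, sa))
    } else if (!is.null(data$inputs)) {
      data <- .load_inputs(data$inputs)
    } else stop("config needs a 'simulate' or 'inputs' block")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  res <- list()
  cs_qc <- stage("qc", qcFilter(data$callset, th$qc_min_length,
                                th$qc_min_probes))
  # burden/locus stages test rare calls; the breakpoint GWAS works from
  # the QC'd calls and applies the <1% rarity bound per breakpoint
  cs <- stage("rare", filterRare(cs_qc, th$max_freq, th$ro_threshold))
  res$callset <- cs
  smp <- sampleTable(cs)

  res$profiles <- stage("burden",
    burdenProfiles(cs, genes = data$genes, constraint = data$constraint))
  res$burden <- stage("burden", burdenPanel(res$profiles, smp))
  res$burden_by_type <- stage("burden", partitionBurden(cs, "type"))
  res$burden_by_length <- stage("burden", partitionBurden(cs, "length"))
  res$burden_by_freq <- stage("burden", partitionBurden(cs, "frequency"))

  if (!is.null(data$syndromic))
    res$locus_syndromic <- stage("locus",
      locusScan(cs, data$syndromic, exons = data$exons))
  if (!is.null(data$pleiotropic))
    res$locus_pleiotropic <- stage("locus",
      locusScan(cs, data$pleiotropic, exons = data$exons))
  if (!is.null(data$syndromic) && "bmi_lowest" %in% colnames(smp)) {
    res$bmi_cases <- stage("bmi",
      bmiLinear(cs, data$syndromic, data$exons, "cases"))
    res$bmi_controls <- stage("bmi",
      bmiLinear(cs, data$syndromic, data$exons, "controls"))
  }

  for (model in c("dup_only", "del_only")) {
    bm <- stage("gwas", filterRareBreakpoints(
      encodeBreakpoints(cs_qc, model), th$max_freq))
    sc <- stage("gwas", scanBreakpoints(bm, smp))
    res[[paste0("scan_", model)]] <- sc
    res[[paste0("cnvr_", model)]] <- stage("cnvr",
      clumpCnvrs(sc, bm, cs_qc, data$probes, genes = data$genes,
                 constraint = data$constraint, p_lead = th$p_lead,
                 r2_min = th$r2_min, window = th$window,
                 min_length = th$cnvr_min_length,
                 min_probes = th$cnvr_min_probes))
  }
  res$cnvr <- rbind(res$cnvr_dup_only, res$cnvr_del_only)
  res$mirror <- stage("mirror",
    mirrorScan(res$scan_dup_only, res$scan_del_only, th$mirror_window))
  res$power <- stage("power",
    powerTable(sum(smp$status == 1), sum(smp$status == 0)))
  res$filter_log <- do.call(rbind, lapply(filterLog(cs), as.data.frame))

  .tsv(res$profiles, out_dir, "burden_profiles.tsv")
  .tsv(res$burden, out_dir, "burden_results.tsv")
  .tsv(rbind(res$burden_by_type, res$burden_by_length,
             res$burden_by_freq), out_dir, "burden_partition.tsv")
  if (!is.null(res$locus_syndromic))
    .tsv(res$locus_syndromic, out_dir, "locus_syndromic.tsv")
  if (!is.null(res$locus_pleiotropic))
    .tsv(res$locus_pleiotropic, out_dir, "locus_pleiotropic.tsv")
  if (!is.null(res$bmi_cases))
    .tsv(rbind(res$bmi_cases, res$bmi_controls), out_dir,
         "bmi_results.tsv")
  .tsv(res$scan_dup_only, out_dir, "breakpoints_dup.tsv")
  .tsv(res$scan_del_only, out_dir, "breakpoints_del.tsv")
  .tsv(res$cnvr, out_dir, "cnvr.tsv")
  if (nrow(res$cnvr))
    write.table(data.frame(chrom = res$cnvr$chrom,
                           start = res$cnvr$start - 1L,
                           end = res$cnvr$end, name = res$cnvr$cnvr_id),
                file.path(out_dir, "cnvr.bed"), quote = FALSE,
                sep = "\t", row.names = FALSE, col.names = FALSE)
  .tsv(res$mirror, out_dir, "mirror.tsv")
  .tsv(res$power, out_dir, "power.tsv")
  .tsv(res$filter_log, out_dir, "run_log.tsv")
  yaml::write_yaml(th, file.path(out_dir, "thresholds_used.yaml"))
  invisible(res)
}
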