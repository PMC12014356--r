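#' @importFrom Matrix sparseMatrix colSums t crossprod
NULL

#' Enumerate unique CNV breakpoints
#'
#' Returns every unique start/end position of a called CNV as a width-1
#' `GRanges`, sorted, with metadata `origin` (`"start"` if any call
#' starts there, else `"end"`). Both CNV types contribute; the resulting
#' positions are shared by the duplication-only and deletion-only
#' encodings.
#'
#' @param x a QC'd [CnvCallSet-class].
#' @return `GRanges` of breakpoint positions.
#' @export
enumerateBreakpoints <- function(x) {
  gr <- cnvCalls(x)
  if (!length(gr)) return(GRanges())
  df <- rbind(data.frame(chrom = as.character(seqnames(gr)),
                         pos = start(gr), origin = "start"),
              data.frame(chrom = as.character(seqnames(gr)),
                         pos = end(gr), origin = "end"))
  df <- df[order(df$chrom, df$pos, df$origin), ]  # "start" sorts last? no: e<s
  # prefer "start" when a position is both a start and an end
  df <- df[order(df$chrom, df$pos, df$origin != "start"), ]
  df <- df[!duplicated(df[c("chrom", "pos")]), ]
  GRanges(df$chrom, IRanges(df$pos, width = 1L), origin = df$origin)
}

#' Encode a call set as a sparse breakpoint pseudo-genotype matrix
#'
#' Builds the samples-by-breakpoints [BreakpointMatrix-class] for one
#' CNV-type model. A breakpoint position `p` is covered by a call
#' `[s, e]` iff `s <= p <= e`, so every call is an observation at both
#' of its own breakpoints. A sample is ALT at `p` if at least one call
#' of the model's type covers `p` (extra copies do not matter), MISSING
#' if only opposite-type calls cover it, REF otherwise; a sample covered
#' by both types is ALT (the model's own type takes precedence).
#'
#' @param x a QC'd [CnvCallSet-class].
#' @param model `"dup_only"` or `"del_only"`.
#' @param bps breakpoint `GRanges` (default: [enumerateBreakpoints()]).
#' @return a [BreakpointMatrix-class].
#' @export
encodeBreakpoints <- function(x, model = c("dup_only", "del_only"),
                              bps = NULL) {
  model <- match.arg(model)
  if (is.null(bps)) bps <- enumerateBreakpoints(x)
  gr <- cnvCalls(x)
  ids <- sampleTable(x)$sample_id
  si <- match(mcols(gr)$sample_id, ids)
  mtype <- if (model == "dup_only") "DUP" else "DEL"
  hits <- findOverlaps(bps, gr)   # width-1 queries: closed-coverage rule
  bp_i <- queryHits(hits); call_j <- subjectHits(hits)
  same <- mcols(gr)$cnv_type[call_j] == mtype
  pair_id <- function(b, s) b * (length(ids) + 1) + s
  alt_b <- bp_i[same]; alt_s <- si[call_j[same]]
  dup <- duplicated(pair_id(alt_b, alt_s))
  alt_b <- alt_b[!dup]; alt_s <- alt_s[!dup]
  opp_b <- bp_i[!same]; opp_s <- si[call_j[!same]]
  dup <- duplicated(pair_id(opp_b, opp_s))
  opp_b <- opp_b[!dup]; opp_s <- opp_s[!dup]
  # MISSING = covered by opposite type only (ALT takes precedence)
  is_alt <- pair_id(opp_b, opp_s) %in% pair_id(alt_b, alt_s)
  mis_b <- opp_b[!is_alt]; mis_s <- opp_s[!is_alt]
  dims <- c(length(ids), length(bps))
  alt <- sparseMatrix(i = alt_s, j = alt_b, x = 1, dims = dims)
  mis <- sparseMatrix(i = mis_s, j = mis_b, x = 1, dims = dims)
  new("BreakpointMatrix", alt = as(alt, "CsparseMatrix"),
      missing = as(mis, "CsparseMatrix"), breakpoints = bps,
      model = model, sample_id = as.character(ids))
}

#' Per-breakpoint ALT counts and frequencies
#'
#' Frequency is the ALT count over the number of non-MISSING samples at
#' that breakpoint. Columns where every sample is MISSING get `NA`
#' frequency with a warning.
#'
#' @param bm a [BreakpointMatrix-class].
#' @return `data.frame` with `alt_count`, `n_nonmissing`, `freq`.
#' @export
breakpointFrequency <- function(bm) {
  ac <- Matrix::colSums(altMatrix(bm))
  nm <- nrow(altMatrix(bm)) - Matrix::colSums(missingMatrix(bm))
  if (any(nm == 0)) warning(sum(nm == 0), " all-MISSING breakpoint column(s)")
  data.frame(alt_count = as.integer(ac), n_nonmissing = as.integer(nm),
             freq = ifelse(nm > 0, ac / nm, NA_real_))
}

#' Restrict a breakpoint matrix to rare, testable breakpoints
#'
#' Keeps breakpoints with frequency strictly below `max_freq` (default
#' the <1% rarity bound), at least one ALT observation (a zero-ALT
#' column is untestable) and at least one non-MISSING sample.
#'
#' @inheritParams breakpointFrequency
#' @param max_freq frequency bound (exclusive).
#' @return the filtered [BreakpointMatrix-class].
#' @export
filterRareBreakpoints <- function(bm, max_freq = 0.01) {
  fr <- suppressWarnings(breakpointFrequency(bm))
  keep <- which(!is.na(fr$freq) & fr$freq < max_freq & fr$alt_count > 0)
  new("BreakpointMatrix", alt = altMatrix(bm)[, keep, drop = FALSE],
      missing = missingMatrix(bm)[, keep, drop = FALSE],
      breakpoints = breakpoints(bm)[keep], model = bpModel(bm),
      sample_id = bm@sample_id)
}

.sparse_col_idx <- function(M) {
  # 0-based row indices per column of a dgCMatrix (empty columns kept)
  dp <- diff(M@p)
  f <- factor(rep.int(seq_along(dp), dp), levels = seq_along(dp))
  unname(split(M@i, f))
}

#' Genome-wide Firth association scan over rare breakpoints
#'
#' Tests each breakpoint's ALT-carrier status against case-control
#' status, adjusted for cohort and ancestry-PC covariates, with MISSING
#' samples excluded from that breakpoint's test. The default engine fits
#' the covariate-only Firth null model once and then performs a
#' one-parameter penalized-likelihood-ratio test of the carrier
#' coefficient with the null linear predictor as offset (the two-stage
#' design of genome-wide scans; MISSING non-carriers cancel from the
#' LRT). `engine = "joint"` refits the full Firth model per breakpoint
#' instead; the two agree closely and the joint fit is used downstream
#' to report lead odds ratios with profile CIs.
#'
#' @param bm a rare-filtered [BreakpointMatrix-class].
#' @param samples sample table with `status` and covariates.
#' @param covariates covariate columns.
#' @param engine `"offset"` (fast two-stage, default) or `"joint"`.
#' @return `data.frame`, one row per breakpoint: `chrom`, `pos`,
#'   `origin`, `model`, carrier counts by status, `freq`, `beta`, `OR`,
#'   `se`, `p_two_sided`, `p_one_sided`, `converged`; the Bonferroni
#'   threshold `0.05 / n_tested` is attached as
#'   `attr(, "bonferroni_alpha")`.
#' @export
scanBreakpoints <- function(bm, samples,
                            covariates = c("cohort", "pc1"),
                            engine = c("offset", "joint")) {
  engine <- match.arg(engine)
  df <- as.data.frame(samples)
  stopifnot(identical(as.character(df$sample_id), bm@sample_id))
  y <- as.numeric(df$status)
  Xb <- .assoc_design(df, covariates)
  alt_idx <- .sparse_col_idx(altMatrix(bm))
  mis_idx <- .sparse_col_idx(missingMatrix(bm))
  if (engine == "offset") {
    null <- .firth_newton(Xb, y)
    eta0 <- drop(Xb %*% null$beta)
    r <- .firth_offset_scan(eta0, y, alt_idx)
    n_used <- nrow(Xb) - lengths(mis_idx)
  } else {
    r <- .firth_scan(Xb, y, alt_idx, mis_idx)
    n_used <- r[, "n_used"]
  }
  bp <- breakpoints(bm)
  st <- y == 1
  alt_case <- vapply(alt_idx, function(i) sum(st[i + 1L]), 0)
  fr <- breakpointFrequency(bm)
  out <- data.frame(chrom = as.character(seqnames(bp)), pos = start(bp),
                    origin = mcols(bp)$origin, model = bpModel(bm),
                    alt_case = as.integer(alt_case),
                    alt_control = as.integer(fr$alt_count - alt_case),
                    n_used = as.integer(n_used), freq = fr$freq,
                    beta = r[, "beta"], OR = exp(r[, "beta"]),
                    se = r[, "se"], p_two_sided = r[, "p_two_sided"],
                    converged = r[, "converged"] == 1,
                    stringsAsFactors = FALSE)
  out$p_one_sided <- ifelse(out$beta > 0, out$p_two_sided / 2,
                            1 - out$p_two_sided / 2)
  attr(out, "bonferroni_alpha") <- 0.05 / nrow(out)
  out
}

#' Missing-aware r-squared between two breakpoints
#'
#' Squared Pearson correlation of the ALT indicators over the samples
#' non-MISSING at both breakpoints. If either indicator is constant on
#' the shared support the correlation is undefined and 0 is returned
#' with attribute `undefined = TRUE`.
#'
#' @param bm a [BreakpointMatrix-class].
#' @param i,j column indices.
#' @return r-squared in `[0, 1]`.
#' @export
ldR2 <- function(bm, i, j) {
  alt_idx <- .sparse_col_idx(altMatrix(bm))
  mis_idx <- .sparse_col_idx(missingMatrix(bm))
  .ld_r2_idx(alt_idx[[i]], alt_idx[[j]], mis_idx[[i]], mis_idx[[j]],
             nrow(altMatrix(bm)))
}

.ld_r2_idx <- function(ai, aj, mi, mj, n_samples) {
  mis <- union(mi, mj)
  n <- n_samples - length(mis)
  xi <- setdiff(ai, mis)
  xj <- setdiff(aj, mis)
  sx <- length(xi); sy <- length(xj)
  sxy <- length(intersect(xi, xj))
  vx <- n * sx - sx^2
  vy <- n * sy - sy^2
  if (n < 2 || vx == 0 || vy == 0)
    return(structure(0, undefined = TRUE))
  num <- (n * sxy - sx * sy)^2
  num / (vx * vy)
}

#' Define CNV regions by greedy r-squared clumping of scan results
#'
#' Nominally significant (`p <= p_lead`) rare breakpoints are processed
#' in order of ascending p (ties broken by smaller genomic position).
#' The best remaining breakpoint becomes a lead; every breakpoint within
#' `window` bp on the same chromosome with `r2 >= r2_min` to the lead is
#' assigned to it (and, if itself a candidate, removed from candidacy).
#' The CNV region (CNVR) spans the minimum to maximum position over the
#' lead and its assigned breakpoints. Emitted CNVRs must be at least
#' `min_length` bp long, span at least `min_probes` probe-map probes and
#' have a risk-direction lead (`OR > 1`). Each CNVR is annotated with
#' carrier counts (samples with a model-type call overlapping the span),
#' a joint-model Firth refit of the lead with profile CI, intersecting
#' genes, and maximum constraint scores plus the constrained-base
#' proportion over the span.
#'
#' @param scan result of [scanBreakpoints()].
#' @param bm the scanned [BreakpointMatrix-class].
#' @param x the rare-filtered [CnvCallSet-class] behind `bm`.
#' @param probes probe-map `GRanges`.
#' @param genes optional gene `GRanges` (`gene_id`).
#' @param constraint optional list of constraint tracks (`phylop`,
#'   `phastcons`) with `cons_score`.
#' @param p_lead lead eligibility threshold (`p <= p_lead`).
#' @param r2_min r-squared threshold for assignment.
#' @param window half-window in bp around the lead.
#' @param min_length,min_probes CNVR filters.
#' @param covariates covariates for the lead refit.
#' @param phylop,phastcons constraint thresholds for the constrained
#'   proportion.
#' @return `data.frame` of CNVRs (possibly 0 rows): `cnvr_id`, `chrom`,
#'   `start`, `end`, `model`, `lead_pos`, `length_kb`, `n_probes`,
#'   `n_case_carriers`, `n_control_carriers`, `OR`, `ci_low`, `ci_high`,
#'   `p_two_sided`, `genes`, `max_phylop`, `max_phastcons`,
#'   `constrained_prop`.
#' @export
clumpCnvrs <- function(scan, bm, x, probes, genes = NULL,
                       constraint = NULL, p_lead = 0.05, r2_min = 0.5,
                       window = 3e5, min_length = 20000, min_probes = 10L,
                       covariates = c("cohort", "pc1"),
                       phylop = 2.27, phastcons = 0.96) {
  empty <- data.frame(cnvr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      model = character(), lead_pos = integer(),
                      length_kb = numeric(), n_probes = integer(),
                      n_case_carriers = integer(),
                      n_control_carriers = integer(), OR = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_two_sided = numeric(), genes = character(),
                      max_phylop = numeric(), max_phastcons = numeric(),
                      constrained_prop = numeric(),
                      stringsAsFactors = FALSE)
  cand <- which(scan$p_two_sided <= p_lead)
  if (!length(cand)) return(empty)
  ord <- cand[order(scan$p_two_sided[cand], scan$pos[cand])]
  alt_idx <- .sparse_col_idx(altMatrix(bm))
  mis_idx <- .sparse_col_idx(missingMatrix(bm))
  n_samp <- nrow(altMatrix(bm))
  smp <- sampleTable(x)
  gr <- cnvCalls(x)
  mtype <- if (bpModel(bm) == "dup_only") "DUP" else "DEL"
  active <- rep(TRUE, nrow(scan))
  rows <- list()
  for (lead in ord) {
    if (!active[lead]) next
    near <- which(scan$chrom == scan$chrom[lead] &
                  abs(scan$pos - scan$pos[lead]) <= window)
    r2 <- vapply(near, function(j)
      as.numeric(.ld_r2_idx(alt_idx[[lead]], alt_idx[[j]],
                            mis_idx[[lead]], mis_idx[[j]], n_samp)),
      0)
    assigned <- near[r2 >= r2_min | near == lead]
    active[assigned] <- FALSE
    span_start <- min(scan$pos[assigned])
    span_end <- max(scan$pos[assigned])
    len <- span_end - span_start
    if (len < min_length) next
    span <- GRanges(scan$chrom[lead], IRanges(span_start, span_end))
    np <- countOverlaps(span, probes)
    if (np < min_probes) next
    if (scan$beta[lead] <= 0) next   # risk effect required
    # carrier = sample with a model-type call overlapping the span
    ov_calls <- which(mcols(gr)$cnv_type == mtype &
                      countOverlaps(gr, span) > 0)
    carrier_ids <- unique(mcols(gr)$sample_id[ov_calls])
    carrier <- as.integer(smp$sample_id %in% carrier_ids)
    lead_fit <- firthTest(
      as.numeric(seq_len(n_samp) %in% (alt_idx[[lead]] + 1L)),
      smp, covariates, sided = "two", ci = "profile")
    gene_str <- NA_character_
    if (!is.null(genes)) {
      gh <- subsetByOverlaps(genes, span, minoverlap = 1L)
      gene_str <- paste(mcols(gh)$gene_id, collapse = ",")
    }
    maxsc <- function(track) {
      if (is.null(track)) return(NA_real_)
      th <- subsetByOverlaps(track, span)
      if (!length(th)) return(NA_real_)
      max(mcols(th)$cons_score)
    }
    cons_prop <- if (!is.null(constraint$phylop))
      constrainedProportion(span, constraint$phylop, phylop) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      cnvr_id = sprintf("%s_%s_%d", bpModel(bm), scan$chrom[lead],
                        scan$pos[lead]),
      chrom = scan$chrom[lead], start = span_start, end = span_end,
      model = bpModel(bm), lead_pos = scan$pos[lead],
      length_kb = len / 1000, n_probes = as.integer(np),
      n_case_carriers = sum(carrier == 1 & smp$status == 1),
      n_control_carriers = sum(carrier == 1 & smp$status == 0),
      OR = lead_fit$OR, ci_low = lead_fit$ci_low,
      ci_high = lead_fit$ci_high, p_two_sided = lead_fit$p_two_sided,
      genes = gene_str, max_phylop = maxsc(constraint$phylop),
      max_phastcons = maxsc(constraint$phastcons),
      constrained_prop = cons_prop, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Detect mirror-effect breakpoint pairs across the two models
#'
#' Reports pairs of nominally significant breakpoints — one from the
#' duplication-only scan, one from the deletion-only scan — lying within
#' `window` bp of each other on the same chromosome with opposite effect
#' directions (e.g. protective duplication, risk deletion): the
#' signature of a mirror dosage effect.
#'
#' @param scan_dup,scan_del results of [scanBreakpoints()] under the two
#'   models.
#' @param window maximum distance in bp between paired breakpoints.
#' @param p_nominal nominal significance bound (strict `<`).
#' @return `data.frame` of candidate pairs with positions, ORs and
#'   p-values from both models.
#' @export
mirrorScan <- function(scan_dup, scan_del, window = 3e5,
                       p_nominal = 0.05) {
  sd_ <- scan_dup[!is.na(scan_dup$p_two_sided) &
                  scan_dup$p_two_sided < p_nominal, ]
  sl <- scan_del[!is.na(scan_del$p_two_sided) &
                 scan_del$p_two_sided < p_nominal, ]
  out <- list()
  for (i in seq_len(nrow(sd_))) {
    j <- which(sl$chrom == sd_$chrom[i] &
               abs(sl$pos - sd_$pos[i]) <= window &
               sign(sl$beta) != sign(sd_$beta[i]) &
               sl$beta != 0 & sd_$beta[i] != 0)
    if (length(j))
      out[[length(out) + 1L]] <- data.frame(
        chrom = sd_$chrom[i], dup_pos = sd_$pos[i], del_pos = sl$pos[j],
        dup_OR = sd_$OR[i], del_OR = sl$OR[j],
        dup_p = sd_$p_two_sided[i], del_p = sl$p_two_sided[j],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), dup_pos = integer(),
                      del_pos = integer(), dup_OR = numeric(),
                      del_OR = numeric(), dup_p = numeric(),
                      del_p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
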