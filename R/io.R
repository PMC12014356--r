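#' @importFrom utils read.table write.table
NULL

.chrom_label <- function(chr) {
  chr <- as.character(chr)
  chr[chr == "23"] <- "X"
  ifelse(grepl("^chr", chr), chr, paste0("chr", chr))
}

.chrom_plink <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  x[x == "X"] <- "23"
  x
}

#' Read and write PLINK CNV text files
#'
#' `readPlinkCnv()` parses the whitespace-separated PLINK CNV format with
#' header `FID IID CHR BP1 BP2 TYPE SCORE SITES`. `BP1`/`BP2` are 1-based
#' inclusive and are kept as closed `GRanges` intervals, so a call spanning
#' `BP1..BP2` has length `BP2 - BP1 + 1` bp. `TYPE` is the called copy
#' number: 0/1 become `"DEL"`, 3 and above `"DUP"`; copy-neutral `TYPE = 2`
#' is rejected (multi-copy states are collapsed, extra dosage is not
#' modelled downstream). `SITES` is the probe count.
#'
#' @param path path to a `.cnv` text file.
#' @param samples optional sample table (`data.frame`/`DataFrame` with
#'   `sample_id`, `status`, ...). When `NULL`, a minimal table is derived
#'   from the IID column with `status = NA`.
#' @param genome genome build tag.
#' @return `readPlinkCnv()`: a [CnvCallSet-class]. `writePlinkCnv()`:
#'   invisibly, the path written.
#' @examples
#' f <- tempfile(fileext = ".cnv")
#' writeLines(c("FID IID CHR BP1 BP2 TYPE SCORE SITES",
#'              "F1 S1 2 50730001 50770000 1 20 17"), f)
#' cs <- readPlinkCnv(f)
#' GenomicRanges::width(cnvCalls(cs))  # 40000
#' @export
readPlinkCnv <- function(path, samples = NULL, genome = "hg38") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PLINK CNV file: ", path)
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  expect <- c("FID", "IID", "CHR", "BP1", "BP2", "TYPE", "SCORE", "SITES")
  if (!identical(toupper(hdr), expect))
    stop("unexpected PLINK CNV header: ", lines[1])
  body <- lines[-1]
  if (!length(body)) {
    gr <- GRanges(sample_id = character(), cnv_type = character(),
                  n_probes = integer(), score = numeric())
  } else {
    fields <- strsplit(trimws(body), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf != 8L))
      stop("malformed PLINK CNV row at line ",
           which(nf != 8L)[1] + 1L, ": expected 8 fields, got ",
           nf[nf != 8L][1])
    m <- matrix(unlist(fields), ncol = 8L, byrow = TRUE)
    bp1 <- suppressWarnings(as.numeric(m[, 4]))
    bp2 <- suppressWarnings(as.numeric(m[, 5]))
    type <- suppressWarnings(as.integer(m[, 6]))
    sites <- suppressWarnings(as.integer(m[, 8]))
    bad <- which(is.na(bp1) | is.na(bp2) | is.na(type) | is.na(sites))
    if (length(bad))
      stop("malformed PLINK CNV row at line ", bad[1] + 1L, ": ", body[bad[1]])
    if (any(type == 2L))
      stop("TYPE = 2 (copy-neutral) at line ",
           which(type == 2L)[1] + 1L, ": not a CNV")
    if (any(bp1 >= bp2))
      stop("zero-length call (BP1 >= BP2) at line ",
           which(bp1 >= bp2)[1] + 1L)
    gr <- GRanges(.chrom_label(m[, 3]), IRanges(bp1, bp2),
                  sample_id = m[, 2],
                  cnv_type = ifelse(type < 2L, "DEL", "DUP"),
                  n_probes = sites,
                  score = suppressWarnings(as.numeric(m[, 7])))
    mcols(gr)$fid <- m[, 1]
  }
  if (is.null(samples))
    samples <- DataFrame(sample_id = unique(mcols(gr)$sample_id),
                         status = NA_integer_)
  CnvCallSet(gr, samples, genome = genome)
}

#' @rdname readPlinkCnv
#' @param x a `CnvCallSet`.
#' @export
writePlinkCnv <- function(x, path) {
  gr <- cnvCalls(x)
  mc <- mcols(gr)
  fid <- if ("fid" %in% names(mc)) mc$fid else mc$sample_id
  df <- data.frame(FID = fid, IID = mc$sample_id,
                   CHR = .chrom_plink(seqnames(gr)),
                   BP1 = start(gr), BP2 = end(gr),
                   TYPE = ifelse(mc$cnv_type == "DEL", 1L, 3L),
                   SCORE = ifelse(is.na(mc$score), 0, mc$score),
                   SITES = mc$n_probes)
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' Read and write the companion sample table
#'
#' Tab-separated with header; requires `sample_id`, `status` (1 = case,
#' 0 = control) and typically `sex`, `cohort`, `pc1`, optional
#' `bmi_lowest` and `age`.
#'
#' @param path file path.
#' @return `readSampleTable()`: a `DataFrame`.
#' @export
readSampleTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("sample table needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  DataFrame(df)
}

#' @rdname readSampleTable
#' @param samples sample table to write.
#' @export
writeSampleTable <- function(samples, path) {
  write.table(as.data.frame(samples), path, quote = FALSE,
              row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read and write a probe map
#'
#' Tab-separated `chrom`, `position`, `probe_id`; returned as width-1
#' `GRanges` sorted by position, with uniqueness of positions per
#' chromosome enforced.
#' @param path file path.
#' @return `readProbeMap()`: a `GRanges` of probe positions.
#' @export
readProbeMap <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  gr <- GRanges(.chrom_label(df$chrom), IRanges(df$position, width = 1L),
                probe_id = as.character(df$probe_id))
  gr <- sort(gr)
  if (any(duplicated(paste(seqnames(gr), start(gr)))))
    stop("duplicate probe positions within a chromosome")
  gr
}

#' @rdname readProbeMap
#' @param probes probe `GRanges` to write.
#' @export
writeProbeMap <- function(probes, path) {
  write.table(data.frame(chrom = as.character(seqnames(probes)),
                         position = start(probes),
                         probe_id = probes$probe_id),
              path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Annotation readers and writers (BED-backed)
#'
#' Genes, exons, constraint tracks and locus lists travel as BED files
#' (0-based half-open on disk, converted by rtracklayer to 1-based closed
#' `GRanges`). Genes carry `pHaplo`/`pTriplo` as extra columns; constraint
#' intervals carry a numeric `cons_score`; locus lists carry `cnv_type`,
#' `rule` and `sided`.
#'
#' @param path file path.
#' @return a `GRanges` with the respective metadata columns.
#' @name annotationIO
NULL

#' @rdname annotationIO
#' @export
readGeneBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
    extraCols = c(pHaplo = "numeric", pTriplo = "numeric"))
  names(mcols(gr))[names(mcols(gr)) == "name"] <- "gene_id"
  gr
}

#' @rdname annotationIO
#' @export
readExonBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  names(mcols(gr))[names(mcols(gr)) == "name"] <- "gene_id"
  gr
}

#' @rdname annotationIO
#' @export
readConstraintBed <- function(path) {
  rtracklayer::import(path, format = "BED",
    extraCols = c(cons_score = "numeric"))
}

#' @rdname annotationIO
#' @export
readLocusBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
    extraCols = c(cnv_type = "character", rule = "character",
                  sided = "character"))
  names(mcols(gr))[names(mcols(gr)) == "name"] <- "locus_id"
  gr
}

.write_bed_extra <- function(gr, path, name_col, extra_cols) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = as.character(mcols(gr)[[name_col]]))
  for (cc in extra_cols) df[[cc]] <- mcols(gr)[[cc]]
  write.table(df, path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname annotationIO
#' @param gr annotation `GRanges` to write.
#' @export
writeGeneBed <- function(gr, path)
  .write_bed_extra(gr, path, "gene_id", c("pHaplo", "pTriplo"))

#' @rdname annotationIO
#' @export
writeExonBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = mcols(gr)$gene_id)
  write.table(df, path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname annotationIO
#' @export
writeConstraintBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = seq_along(gr), cons_score = mcols(gr)$cons_score)
  write.table(df, path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname annotationIO
#' @export
writeLocusBed <- function(gr, path)
  .write_bed_extra(gr, path, "locus_id", c("cnv_type", "rule", "sided"))
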