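ARM_LEVELS <- c("TNF", "TNF_ACTD", "CONTROL")

#' Validate a count matrix
#'
#' A count matrix is a plain integer matrix with unique gene identifiers as
#' row names and unique sample identifiers as column names. All cells must be
#' non-negative integers.
#'
#' @param counts matrix of read counts, genes in rows.
#' @return the validated matrix (invisibly unchanged), with integer storage.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts))
    stop("counts must be a matrix (genes x samples)")
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("counts must have gene identifiers as row names")
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    stop("counts must have sample identifiers as column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers")
  if (nrow(counts) > 0 && ncol(counts) > 0) {
    if (!is.numeric(counts))
      stop("counts must be numeric")
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(counts))
      stop(sprintf("count for gene '%s', sample '%s' is not a non-negative integer: %s",
                   rownames(counts)[i[1]], colnames(counts)[i[2]],
                   format(counts[bad[1]])))
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read a gene-level count table
#'
#' Expects a tab-separated file with gene identifiers in the first column and
#' a header row of sample identifiers. Gene order is preserved.
#'
#' @param path path to a TSV count table.
#' @return integer count matrix (genes x samples).
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("count table needs a gene-id column")
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 ncol = ncol(m),
                                 dimnames = list(genes, colnames(m))))
  if (nrow(num) > 0) {
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(num))
      stop(sprintf("invalid count for gene '%s', sample '%s': '%s'",
                   genes[i[1]], colnames(num)[i[2]], m[bad[1]]))
    }
  }
  validate_counts(num)
}

#' Write a count table as TSV
#'
#' @param counts integer count matrix.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet describes the chase design: one row per library with
#' columns `sample_id`, `time_h` (hours of TNF stimulation), `arm`
#' (`TNF`, `TNF_ACTD` or `CONTROL`; matched case-insensitively) and
#' `replicate`. Unstimulated `CONTROL` libraries are only allowed at
#' `time_h = 0`.
#'
#' @param path path to a tab- or comma-separated file.
#' @return data.frame with validated columns; `arm` is a factor with levels
#'   TNF, TNF_ACTD, CONTROL.
#' @export
read_sample_sheet <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet data.frame
#' @param sheet data.frame with columns sample_id, time_h, arm, replicate.
#' @return validated data.frame.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "time_h", "arm", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  sheet$time_h <- as.numeric(sheet$time_h)
  if (anyNA(sheet$time_h) || any(sheet$time_h < 0))
    stop("time_h must be non-negative numbers")
  arm <- toupper(gsub("[+. ]", "_", as.character(sheet$arm)))
  arm[arm %in% c("TNF_ACT_D", "TNFACTD", "ACTD")] <- "TNF_ACTD"
  unknown <- setdiff(unique(arm), ARM_LEVELS)
  if (length(unknown))
    stop("unknown arm label(s): ", paste(unknown, collapse = ", "),
         " (expected TNF, TNF_ACTD or CONTROL)")
  sheet$arm <- factor(arm, levels = ARM_LEVELS)
  if (any(sheet$arm == "CONTROL" & sheet$time_h != 0))
    stop("CONTROL samples are only permitted at time_h = 0")
  sheet$replicate <- as.integer(sheet$replicate)
  if (anyNA(sheet$replicate) || any(sheet$replicate < 1))
    stop("replicate must be a positive integer")
  rownames(sheet) <- NULL
  sheet
}

#' Write a sample sheet as TSV
#' @param sheet validated sample sheet.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# check that every sample in counts is described exactly once
match_sheet <- function(counts, sheet) {
  sheet <- validate_sample_sheet(sheet)
  missing <- setdiff(colnames(counts), sheet$sample_id)
  if (length(missing))
    stop("samples in count matrix absent from sample sheet: ",
         paste(missing, collapse = ", "))
  sheet[match(colnames(counts), sheet$sample_id), , drop = FALSE]
}

#' Read a gene-length annotation table
#'
#' Two-column TSV `gene_id<TAB>exonic_length_bp`. Lengths must be positive
#' integers (union of exonic bases, used for RPKM).
#'
#' @param path path to the TSV (a header line is auto-detected).
#' @return named integer vector of lengths in bp.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("annotation must have two columns: gene_id, length_bp")
  if (suppressWarnings(is.na(as.numeric(df[1, 2]))))  # header row present
    df <- df[-1, , drop = FALSE]
  len <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(len) || any(len < 1) || any(len != round(len)))
    stop("exonic lengths must be positive integers")
  if (anyDuplicated(df[[1]])) stop("duplicated gene_id in annotation")
  stats::setNames(as.integer(len), as.character(df[[1]]))
}

#' Derive exonic gene lengths from a BED12 file
#'
#' Sums the widths of the per-gene union of exon blocks (0-based half-open
#' BED coordinates). Requires the rtracklayer / GenomicRanges stack.
#'
#' @param path BED12 file; the `name` field is taken as the gene id.
#' @return named integer vector of exonic lengths in bp.
#' @export
gene_lengths_from_bed12 <- function(path) {
  for (pkg in c("rtracklayer", "GenomicRanges", "IRanges"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("gene_lengths_from_bed12 requires the ", pkg, " package")
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) stop("BED file has no block (exon) structure; need BED12")
  exons <- GenomicRanges::GRangesList(lapply(seq_along(gr), function(i) {
    b <- gr$blocks[[i]]
    GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr)[i]),
                           IRanges::shift(b, GenomicRanges::start(gr)[i] - 1L))
  }))
  names(exons) <- gr$name
  lens <- vapply(split(exons, names(exons)), function(gl) {
    sum(IRanges::width(IRanges::reduce(unlist(IRanges::ranges(gl)))))
  }, integer(1))
  lens
}

#' Compute RPKM expression values
#'
#' Reads per kilobase of exon model per million mapped reads, with the
#' per-sample total taken as the column sum of the supplied count matrix:
#' `rpkm(g, s) = counts(g, s) * 1e9 / (length_bp(g) * total(s))`.
#'
#' @param counts integer count matrix.
#' @param lengths named vector of exonic lengths in bp covering every gene.
#' @return numeric matrix of RPKM values with attribute `unit = "RPKM"`.
#' @export
compute_rpkm <- function(counts, lengths) {
  counts <- validate_counts(counts)
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("no length annotation for gene(s): ", paste(miss, collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(len < 1)) stop("exonic lengths must be >= 1 bp")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  val <- sweep(counts * 1e9 / len, 2, tot, "/")
  attr(val, "unit") <- "RPKM"
  val
}
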