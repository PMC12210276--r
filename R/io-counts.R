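# Readers and writers for the count-matrix side of the data model.
# On-disk conventions: counts as TSV (regions x samples, region id in the
# first column) or MatrixMarket; regions as BED (0-based half-open, 4 columns);
# sample sheets as CSV.

#' Write a region count matrix to TSV + BED (+ optional MatrixMarket)
#'
#' @param x a [region_count_matrix()].
#' @param counts_path TSV output path (`region_id` column then one column per
#'   sample). If the path ends in `.mtx`, MatrixMarket is written instead and
#'   sample ids go to a sidecar `<path>.cols` file.
#' @param bed_path BED output path (chrom, start, end, id; 0-based half-open).
#' @return invisibly, the input.
#' @export
write_counts <- function(x, counts_path, bed_path = NULL) {
  stopifnot(inherits(x, "region_count_matrix"))
  if (grepl("\\.mtx$", counts_path)) {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), counts_path)
    writeLines(colnames(x$counts), paste0(counts_path, ".cols"))
    writeLines(rownames(x$counts), paste0(counts_path, ".rows"))
  } else {
    df <- data.frame(region_id = rownames(x$counts), x$counts,
                     check.names = FALSE)
    utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) write_bed(x$regions, bed_path)
  invisible(x)
}

#' Write regions as BED (0-based, half-open)
#' @param regions data.frame with `chrom`, `start`, `end`, `id`.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(regions)
}

#' Read a BED file of regions
#' @param path BED path (>= 4 columns: chrom, start, end, name).
#' @return data.frame with `chrom`, `start`, `end`, `id` (BED convention kept:
#'   0-based half-open; region length is `end - start`).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED file must have >= 4 columns", call. = FALSE)
  stats::setNames(df[, 1:4], c("chrom", "start", "end", "id"))
}

#' Write / read a sample sheet as CSV
#' @param sheet a [sample_sheet()].
#' @param path CSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(sheet)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Load and cross-validate counts, regions and sample sheet
#'
#' @param counts_path counts TSV (or `.mtx` MatrixMarket with `.cols`/`.rows`
#'   sidecars).
#' @param bed_path BED file of region coordinates, same order/ids as counts.
#' @param sheet_path sample-sheet CSV.
#' @return list with `counts` ([region_count_matrix()], library sizes =
#'   column sums) and `sheet` ([sample_sheet()]).
#' @export
load_counts <- function(counts_path, bed_path, sheet_path) {
  for (p in c(counts_path, bed_path, sheet_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  if (grepl("\\.mtx$", counts_path)) {
    m <- as.matrix(Matrix::readMM(counts_path))
    colnames(m) <- readLines(paste0(counts_path, ".cols"))
    rownames(m) <- readLines(paste0(counts_path, ".rows"))
  } else {
    df <- utils::read.delim(counts_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  regions <- read_bed(bed_path)
  if (!identical(regions$id, rownames(m)))
    stop("region ids in BED do not match count matrix rows", call. = FALSE)
  sheet <- read_sample_sheet(sheet_path)
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing))
    stop("sample(s) in counts but not in sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sheet <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  list(counts = region_count_matrix(regions, m), sheet = sample_sheet(sheet))
}
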