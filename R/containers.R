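#' Region-by-sample count matrix
#'
#' The central container for ATAC-seq read counts: an integer matrix of
#' nonnegative counts over genomic regions (rows) by samples (columns),
#' together with region coordinates (BED convention: 0-based, half-open) and
#' per-sample library sizes (column sums unless overridden).
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`, `id`
#'   (0-based half-open coordinates, unique ids).
#' @param counts numeric matrix of nonnegative integers, `nrow(regions)` rows;
#'   column names are sample ids.
#' @param library_sizes optional positive numeric vector per sample; defaults
#'   to the column sums.
#' @return an object of class `region_count_matrix` with elements `regions`,
#'   `counts`, `samples`, `library_sizes`.
#' @export
region_count_matrix <- function(regions, counts, library_sizes = NULL) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end", "id") %in% names(regions)))
  if (anyDuplicated(regions$id))
    stop("duplicate region ids: ",
         paste(unique(regions$id[duplicated(regions$id)]), collapse = ", "),
         call. = FALSE)
  if (any(regions$start >= regions$end))
    stop("regions must satisfy start < end (BED half-open)", call. = FALSE)
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(regions))
    stop("counts/regions dimension mismatch: ", nrow(counts), " rows vs ",
         nrow(regions), " regions", call. = FALSE)
  if (is.null(colnames(counts)))
    stop("counts must carry sample ids as column names", call. = FALSE)
  if (any(counts < 0)) stop("negative counts found", call. = FALSE)
  if (any(counts != round(counts))) stop("counts must be integers", call. = FALSE)
  rownames(counts) <- regions$id
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes length must equal the number of samples", call. = FALSE)
  if (any(library_sizes <= 0))
    stop("nonpositive library size for sample(s): ",
         paste(colnames(counts)[library_sizes <= 0], collapse = ", "),
         call. = FALSE)
  structure(list(regions = regions, counts = counts,
                 samples = colnames(counts),
                 library_sizes = stats::setNames(as.numeric(library_sizes),
                                                 colnames(counts))),
            class = "region_count_matrix")
}

#' @export
print.region_count_matrix <- function(x, ...) {
  cat("region_count_matrix:", nrow(x$counts), "regions x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' @export
dim.region_count_matrix <- function(x) dim(x$counts)

#' Per-sample design sheet
#'
#' Validates a per-sample table of design factors (diagnosis, cell type,
#' subject, sex) plus any number of candidate numeric nuisance covariates.
#'
#' @param df data.frame with columns `sample_id`, `subject_id`, `cell_type`,
#'   `diagnosis` (`case`/`control`), `sex` (`male`/`female`/`unknown`);
#'   remaining columns are treated as candidate covariates.
#' @return the validated data.frame, classed `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "subject_id", "cell_type", "diagnosis", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in sheet", call. = FALSE)
  bad <- setdiff(unique(df$diagnosis), c("case", "control"))
  if (length(bad)) stop("diagnosis must be case/control; found: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$sex), c("male", "female", "unknown"))
  if (length(bad)) stop("sex must be male/female/unknown; found: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Genotype table
#'
#' Per-variant annotation (`chrom`, `pos` 1-based, `maf`, `is_par`) and a
#' variants-by-samples matrix of calls coded 0/1/2 (ALT allele count) with
#' `NA` for missing.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `maf`, `is_par`.
#' @param calls integer matrix, `nrow(variants)` rows, sample ids as columns.
#' @return classed list `genotype_table`.
#' @export
genotype_table <- function(variants, calls) {
  stopifnot(all(c("chrom", "pos", "maf", "is_par") %in% names(variants)))
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(variants))
    stop("calls/variants dimension mismatch", call. = FALSE)
  if (any(variants$maf < 0 | variants$maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]", call. = FALSE)
  if (any(variants$pos < 1))
    stop("pos must be >= 1 (VCF is 1-based)", call. = FALSE)
  if (!all(calls %in% c(0L, 1L, 2L, NA)))
    stop("calls must be 0/1/2 or NA", call. = FALSE)
  structure(list(variants = variants, calls = calls,
                 samples = colnames(calls)),
            class = "genotype_table")
}

#' Calcium imaging session
#'
#' Cells-by-timepoints dF/F traces at a fixed sampling rate, with optional
#' event intervals (e.g. social-zone occupancy bouts) in seconds.
#'
#' @param traces numeric matrix, cells x timepoints, finite values; row names
#'   are cell ids.
#' @param rate_hz sampling rate (> 0).
#' @param events data.frame with columns `start_s`, `end_s` (may be empty).
#' @param session_id identifier string.
#' @return classed list `calcium_session`.
#' @export
calcium_session <- function(traces, rate_hz, events = NULL, session_id = "session") {
  traces <- as.matrix(traces)
  check_positive(rate_hz, "rate_hz")
  if (!all(is.finite(traces))) {
    bad <- rownames(traces)[!apply(is.finite(traces), 1, all)]
    stop("non-finite values in traces for cell(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(traces)))
    rownames(traces) <- sprintf("cell%04d", seq_len(nrow(traces)))
  duration <- ncol(traces) / rate_hz
  if (is.null(events)) events <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (nrow(events)) {
    if (any(events$end_s <= events$start_s))
      stop("event end_s must exceed start_s", call. = FALSE)
    if (is.unsorted(events$start_s))
      stop("events must be sorted by start_s", call. = FALSE)
    if (any(utils::head(events$end_s, -1) > utils::tail(events$start_s, -1)))
      stop("overlapping events", call. = FALSE)
    if (any(events$start_s < 0) || any(events$end_s > duration))
      stop("events outside the recording [0, ", duration, "] s", call. = FALSE)
  }
  structure(list(cells = rownames(traces), traces = traces, rate_hz = rate_hz,
                 events = events, duration_s = duration,
                 session_id = session_id),
            class = "calcium_session")
}

#' Gene-set collection
#'
#' @param sets named list of character vectors (gene ids).
#' @param universe character vector of all gene ids; every set must be a
#'   subset.
#' @return classed list `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names", call. = FALSE)
  sets <- lapply(sets, unique)
  out <- lapply(sets, setdiff, y = universe)
  stray <- names(out)[vapply(out, length, 1L) > 0]
  if (length(stray))
    stop("set(s) not contained in universe: ", paste(stray, collapse = ", "),
         call. = FALSE)
  structure(list(sets = sets, universe = unique(universe)),
            class = "gene_set_collection")
}
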