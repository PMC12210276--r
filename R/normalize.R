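#' Normalization parameters
#'
#' Holds the filtering and normalization tuning constants: regions are kept
#' when their CPM reaches `cpm_threshold` in at least
#' `ceiling(min_fraction * n_samples)` samples; TMM trims `tmm_trim_M` from
#' each tail of the M-values (log2 sample/reference ratios) and `tmm_trim_A`
#' from each tail of the A-values (average log2 abundance); quantile
#' normalization is applied within groups defined by `quantile_group_key`.
#'
#' @param cpm_threshold CPM cutoff (default 1).
#' @param min_fraction minimum fraction of samples reaching the cutoff
#'   (default 0.10).
#' @param tmm_trim_M M-value trim fraction per tail (default 0.30).
#' @param tmm_trim_A A-value trim fraction per tail (default 0.05).
#' @param quantile_group_key sample-sheet column defining quantile groups
#'   (default `cell_type`).
#' @param prior_count damping count for log-CPM (default 0.5).
#' @return classed list `normalization_params`.
#' @export
normalization_params <- function(cpm_threshold = 1, min_fraction = 0.10,
                                 tmm_trim_M = 0.30, tmm_trim_A = 0.05,
                                 quantile_group_key = "cell_type",
                                 prior_count = 0.5) {
  check_positive(cpm_threshold, "cpm_threshold")
  check_fraction(min_fraction, "min_fraction", lo = 1e-12, hi = 0.5)
  check_fraction(tmm_trim_M, "tmm_trim_M", lo = 1e-12, hi = 0.5)
  check_fraction(tmm_trim_A, "tmm_trim_A", lo = 1e-12, hi = 0.5)
  check_positive(prior_count, "prior_count")
  structure(list(cpm_threshold = cpm_threshold, min_fraction = min_fraction,
                 tmm_trim_M = tmm_trim_M, tmm_trim_A = tmm_trim_A,
                 quantile_group_key = quantile_group_key,
                 prior_count = prior_count),
            class = "normalization_params")
}

#' Counts per million
#'
#' `CPM[r, s] = counts[r, s] / library_sizes[s] * 1e6`.
#'
#' @param x a [region_count_matrix()].
#' @return numeric matrix of CPM values, same dimnames as the counts.
#' @export
cpm_transform <- function(x) {
  stopifnot(inherits(x, "region_count_matrix"))
  zero <- x$library_sizes <= 0
  if (any(zero))
    stop("zero library size for sample(s): ",
         paste(x$samples[zero], collapse = ", "), call. = FALSE)
  sweep(x$counts, 2, x$library_sizes, "/") * 1e6
}

#' Filter regions with low signal
#'
#' Keeps a region iff its CPM reaches `cpm_threshold` in at least
#' `ceiling(min_fraction * n_samples)` samples (the ceiling makes the "at
#' least 10% of samples" rule exact for any cohort size). Region order is
#' preserved; filtering is idempotent.
#'
#' @param x a [region_count_matrix()].
#' @param params a [normalization_params()].
#' @return list with `filtered` ([region_count_matrix()]; original library
#'   sizes retained) and `removed` (character vector of dropped region ids).
#' @export
filter_low_signal <- function(x, params = normalization_params()) {
  cpm <- cpm_transform(x)
  need <- ceiling(params$min_fraction * ncol(cpm))
  keep <- rowSums(cpm >= params$cpm_threshold) >= need
  if (!any(keep))
    stop("no region passes CPM >= ", params$cpm_threshold, " in >= ", need,
         " samples; lower cpm_threshold or min_fraction", call. = FALSE)
  filtered <- region_count_matrix(x$regions[keep, , drop = FALSE],
                                  x$counts[keep, , drop = FALSE],
                                  library_sizes = x$library_sizes)
  list(filtered = filtered, removed = x$regions$id[!keep])
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values scaling factors (relative effective library-size
#' adjustments), computed by `edgeR::calcNormFactors(method = "TMM")`:
#' M- and A-values on regions nonzero in both the sample and the reference,
#' doubly trimmed (`tmm_trim_M`, `tmm_trim_A` per tail), combined by an
#' inverse-asymptotic-variance weighted mean, and rescaled so the factors'
#' geometric mean is 1. The automatic reference is the sample whose
#' 75th-percentile CPM is closest to the mean of those percentiles.
#'
#' @param x a [region_count_matrix()].
#' @param params a [normalization_params()].
#' @param reference sample id, or `"auto"`.
#' @return named numeric vector of factors (geometric mean 1).
#' @export
tmm_factors <- function(x, params = normalization_params(),
                        reference = "auto") {
  stopifnot(inherits(x, "region_count_matrix"))
  if (ncol(x$counts) < 2L) stop("TMM needs >= 2 samples", call. = FALSE)
  if (any(colSums(x$counts > 0) == 0L))
    stop("sample(s) with no nonzero region", call. = FALSE)
  ref_col <- NULL
  if (!identical(reference, "auto")) {
    ref_col <- match(reference, x$samples)
    if (is.na(ref_col)) stop("unknown reference sample: ", reference,
                             call. = FALSE)
  }
  f <- edgeR::calcNormFactors(x$counts, lib.size = x$library_sizes,
                              method = "TMM", refColumn = ref_col,
                              logratioTrim = params$tmm_trim_M,
                              sumTrim = params$tmm_trim_A)
  stats::setNames(as.numeric(f), x$samples)
}

#' Quantile-normalize columns within groups
#'
#' Within each group of samples, every column's sorted values are replaced by
#' the cross-sample mean of order statistics; ties receive the mean of their
#' target quantiles (via `limma::normalizeQuantiles(ties = TRUE)`). Groups of
#' size 1 are passed through with a warning.
#'
#' @param values numeric region x sample matrix.
#' @param groups vector/factor of group labels per sample (column).
#' @return matrix of the same shape.
#' @export
quantile_normalize_within_group <- function(values, groups) {
  values <- as.matrix(values)
  if (length(groups) != ncol(values))
    stop("groups length must match number of columns", call. = FALSE)
  out <- values
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) == 1L) {
      warning("group '", g, "' has a single sample; passed through unchanged")
      next
    }
    out[, idx] <- limma::normalizeQuantiles(values[, idx, drop = FALSE],
                                            ties = TRUE)
  }
  out
}

#' Full normalization pipeline: TMM-scaled log-CPM, then within-group
#' quantile normalization
#'
#' Computes log2 CPM with TMM-adjusted effective library sizes
#' (`library_size * tmm_factor`) and a damping prior count, then quantile
#' normalizes within the sample groups given by `params$quantile_group_key`
#' (cell type by default, so read distributions are balanced across samples
#' of the same cell type without forcing the two cell types onto a common
#' distribution).
#'
#' @param x a filtered [region_count_matrix()].
#' @param sheet a [sample_sheet()] covering the matrix's samples.
#' @param params a [normalization_params()].
#' @return list with `norm` (region x sample normalized log2-CPM matrix),
#'   `tmm` (factors) and `effective_lib` (effective library sizes).
#' @export
normalize_pipeline <- function(x, sheet, params = normalization_params()) {
  stopifnot(inherits(x, "region_count_matrix"))
  sheet <- sheet[match(x$samples, sheet$sample_id), , drop = FALSE]
  f <- tmm_factors(x, params)
  eff <- x$library_sizes * f
  logcpm <- edgeR::cpm(x$counts, lib.size = eff, log = TRUE,
                       prior.count = params$prior_count)
  groups <- sheet[[params$quantile_group_key]]
  if (is.null(groups))
    stop("sheet has no column '", params$quantile_group_key, "'", call. = FALSE)
  norm <- quantile_normalize_within_group(logcpm, groups)
  dimnames(norm) <- dimnames(x$counts)
  list(norm = norm, tmm = f, effective_lib = eff)
}
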