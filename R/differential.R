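# Precision-weighted differential accessibility. The per-region model is the
# cell type x diagnosis interaction plus sex, fitted by weighted least
# squares with (i) observation-level precision weights from the mean-variance
# trend, (ii) per-sample quality weights, and (iii) an exchangeable
# intra-subject correlation handled as a consensus-correlation GLS (the
# practical weighted-LS reading of a subject random intercept). Variances are
# moderated by empirical Bayes before the contrast test; q-values are BH.

#' Build the base design matrix and a within-cell-type contrast
#'
#' @param sheet a [sample_sheet()].
#' @param contrast string `"case_vs_control@<cell_type>"`; the contrast
#'   compares case minus control within that cell type.
#' @return list with `design` (matrix), `contrast` (numeric vector over
#'   design columns), `block` (subject ids per sample).
#' @export
design_spec <- function(sheet, contrast) {
  X <- base_design(sheet)
  parts <- strsplit(contrast, "@", fixed = TRUE)[[1]]
  if (length(parts) != 2L || parts[1] != "case_vs_control")
    stop("contrast must look like 'case_vs_control@<cell_type>'",
         call. = FALSE)
  ct <- parts[2]
  col_case <- paste0("ctdx", ct, ".case")
  col_ctrl <- paste0("ctdx", ct, ".control")
  if (!all(c(col_case, col_ctrl) %in% colnames(X)))
    stop("cell type '", ct, "' with both diagnoses not present in the design",
         call. = FALSE)
  cvec <- stats::setNames(numeric(ncol(X)), colnames(X))
  cvec[col_case] <- 1; cvec[col_ctrl] <- -1
  list(design = X, contrast = cvec, block = sheet$subject_id)
}

#' Observation-level precision weights from the mean-variance trend
#'
#' Fits each region by OLS, lowess-smooths the square-root residual standard
#' deviation against average abundance, evaluates the trend at each fitted
#' value and returns `trend^-4` as strictly positive observation weights
#' (high-variance observations are down-weighted; for count-derived log-CPM
#' the variance falls with abundance, so weights rise with abundance).
#'
#' @param norm region x sample normalized matrix (>= 10 regions).
#' @param design design matrix.
#' @param span lowess span (default 0.5).
#' @return matrix of weights, same shape as `norm`.
#' @export
estimate_precision_weights <- function(norm, design, span = 0.5) {
  if (nrow(norm) < 10L)
    stop("need >= 10 regions to estimate the mean-variance trend",
         call. = FALSE)
  fit <- limma::lmFit(norm, design)
  if (min(fit$df.residual) < 1L)
    stop("no residual degrees of freedom", call. = FALSE)
  sx <- rowMeans(norm)
  sy <- sqrt(fit$sigma)
  lo <- stats::lowess(sx, sy, f = span)
  trend <- stats::approxfun(lo$x, lo$y, rule = 2)
  fitted_vals <- fit$coefficients %*% t(design)
  w <- trend(fitted_vals)^-4
  w[!is.finite(w) | w <= 0] <- min(w[is.finite(w) & w > 0])
  matrix(w, nrow(norm), ncol(norm), dimnames = dimnames(norm))
}

#' Per-sample quality weights
#'
#' Estimates each sample's relative residual variance as the mean squared
#' standardized OLS residual across regions and returns the inverse, rescaled
#' to geometric mean 1. A sample with inflated noise receives the smallest
#' weight.
#'
#' @param norm region x sample matrix (>= 3 samples).
#' @param design design matrix.
#' @return named numeric vector of weights (geometric mean 1).
#' @export
estimate_sample_weights <- function(norm, design) {
  if (ncol(norm) < 3L) stop("need >= 3 samples", call. = FALSE)
  fit <- limma::lmFit(norm, design)
  res <- norm - fit$coefficients %*% t(design)
  std <- res / fit$sigma           # rows standardized by per-region sd
  v <- colMeans(std^2)
  w <- 1 / v
  w <- w / geo_mean(w)
  stats::setNames(w, colnames(norm))
}

#' Consensus intra-block correlation
#'
#' Per region, estimates the correlation among residuals of samples sharing a
#' block (subject): the mean cross-product over all within-block pairs
#' divided by the mean squared residual. Region estimates are combined by the
#' median on the variance-stabilizing atanh scale. Returns 0 with a warning
#' when no block holds more than one sample.
#'
#' @param norm region x sample matrix.
#' @param design design matrix.
#' @param block vector of block (subject) ids per sample.
#' @return consensus correlation in `(-1, 1)`.
#' @export
estimate_block_correlation <- function(norm, design, block) {
  block <- as.character(block)
  tab <- table(block)
  multi <- names(tab)[tab >= 2]
  if (!length(multi)) {
    warning("no block holds >= 2 samples; returning correlation 0")
    return(0)
  }
  fit <- limma::lmFit(norm, design)
  res <- norm - fit$coefficients %*% t(design)
  pairs <- do.call(rbind, lapply(multi, function(b) {
    idx <- which(block == b)
    t(utils::combn(idx, 2))
  }))
  rho <- vapply(seq_len(nrow(norm)), function(r) {
    e <- res[r, ]
    s2 <- mean(e^2)
    if (s2 <= 0) return(NA_real_)
    cp <- mean(e[pairs[, 1]] * e[pairs[, 2]])
    max(min(cp / s2, 0.99), -0.99)
  }, numeric(1))
  rho <- rho[is.finite(rho)]
  tanh(stats::median(atanh(rho)))
}

#' Fit the weighted differential model and test a contrast
#'
#' Generalized least squares per region with combined observation x sample
#' weights and an exchangeable intra-block correlation (via `limma::lmFit`
#' with `block`/`correlation`), followed by empirical-Bayes variance
#' moderation (`limma::eBayes`) and a BH-adjusted two-sided test of the
#' contrast. Set `moderate = FALSE` for ordinary (unmoderated) t-statistics.
#'
#' @param norm region x sample normalized matrix.
#' @param design_spec list from [design_spec()] (or a list with `design`,
#'   `contrast`, `block`).
#' @param obs_weights optional observation-weight matrix
#'   ([estimate_precision_weights()]).
#' @param sample_weights optional per-sample weights
#'   ([estimate_sample_weights()]).
#' @param block_correlation consensus correlation
#'   ([estimate_block_correlation()]); 0 disables the GLS blocking.
#' @param moderate empirical-Bayes moderation switch (default TRUE).
#' @return data.frame (classed `differential_table`): `region`, `logFC`, `t`,
#'   `p_value`, `q_value`, `ave_expr`.
#' @export
fit_differential <- function(norm, design_spec, obs_weights = NULL,
                             sample_weights = NULL, block_correlation = 0,
                             moderate = TRUE) {
  X <- design_spec$design
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design", call. = FALSE)
  w <- NULL
  if (!is.null(obs_weights)) w <- obs_weights
  if (!is.null(sample_weights)) {
    sw <- matrix(sample_weights, nrow(norm), ncol(norm), byrow = TRUE)
    w <- if (is.null(w)) sw else w * sw
  }
  if (abs(block_correlation) > 1e-12) {
    fit <- limma::lmFit(norm, X, weights = w, block = design_spec$block,
                        correlation = block_correlation)
  } else {
    fit <- limma::lmFit(norm, X, weights = w)
  }
  fit2 <- limma::contrasts.fit(fit, contrasts = design_spec$contrast)
  if (moderate) {
    fit2 <- limma::eBayes(fit2)
    tt <- fit2$t[, 1]
    p <- fit2$p.value[, 1]
  } else {
    tt <- fit2$coefficients[, 1] / (fit2$stdev.unscaled[, 1] * fit2$sigma)
    p <- 2 * stats::pt(-abs(tt), df = fit2$df.residual)
  }
  ids <- rownames(norm) %||% sprintf("region%05d", seq_len(nrow(norm)))
  out <- data.frame(region = ids,
                    logFC = fit2$coefficients[, 1],
                    t = tt,
                    p_value = p,
                    q_value = bh_adjust(p),
                    ave_expr = rowMeans(norm),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values with monotonicity enforcement (via
#' `stats::p.adjust(method = "BH")`); input order preserved.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}
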