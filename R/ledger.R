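# BIC covariate-selection "ledger": for every candidate sample-level
# covariate, compare per-region OLS fits of the base design (cell type x
# diagnosis interaction + sex) with and without the candidate, and admit the
# candidate only if at least `min_fraction` of regions improve the BIC by at
# least `delta_bic` ("positive" evidence).

#' Ledger configuration
#'
#' @param candidates character vector of sample-sheet column names to screen.
#' @param delta_bic BIC improvement threshold (default 4; the grid report also
#'   evaluates 2 and 10).
#' @param min_fraction minimum fraction of regions whose BIC must improve by
#'   `delta_bic` (default 0.05; grid also evaluates 0.02).
#' @param base_terms character vector of base model terms (default the cell
#'   type x diagnosis interaction plus sex).
#' @return classed list `ledger_config`.
#' @export
ledger_config <- function(candidates, delta_bic = 4, min_fraction = 0.05,
                          base_terms = c("cell_type:diagnosis", "sex")) {
  check_positive(delta_bic, "delta_bic")
  check_fraction(min_fraction, "min_fraction", lo = 1e-12)
  if (any(candidates %in% c("cell_type", "diagnosis", "sex")))
    stop_field("candidates", "must be disjoint from the base design terms")
  structure(list(candidates = candidates, delta_bic = delta_bic,
                 min_fraction = min_fraction, base_terms = base_terms),
            class = "ledger_config")
}

# base design matrix: one column per cell_type x diagnosis level + sex
# (sex omitted for single-sex cohorts, where it is inestimable)
base_design <- function(sheet) {
  ctdx <- interaction(sheet$cell_type, sheet$diagnosis, drop = TRUE, sep = ".")
  if (length(unique(sheet$sex)) < 2L)
    return(stats::model.matrix(~ 0 + ctdx, data.frame(ctdx = ctdx)))
  stats::model.matrix(~ 0 + ctdx + sex,
                      data = data.frame(ctdx = ctdx, sex = factor(sheet$sex)))
}

#' BIC of an OLS fit for one region
#'
#' Gaussian-likelihood BIC of an ordinary least-squares fit:
#' `BIC = n * log(RSS / n) + k * log(n)` with `k` counting all estimated
#' coefficients plus the residual variance. The RSS is floored at 1e-12 (with
#' a warning) so perfect fits do not yield `-Inf`.
#'
#' @param values numeric response vector (per-sample normalized values for
#'   one region).
#' @param design_matrix numeric design matrix, full column rank.
#' @return BIC score (smaller is better).
#' @export
region_bic <- function(values, design_matrix) {
  X <- as.matrix(design_matrix)
  n <- length(values)
  if (n <= ncol(X))
    stop("need n_samples > n_parameters", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  rss <- sum(qr.resid(qr_x, values)^2)
  if (rss < 1e-12) {
    warning("RSS below 1e-12 floored (near-perfect fit)")
    rss <- 1e-12
  }
  n * log(rss / n) + (ncol(X) + 1) * log(n)
}

# per-region RSS for all regions at once (Y: regions x samples)
all_region_rss <- function(Y, X) {
  qr_x <- qr(X)
  res <- qr.resid(qr_x, t(Y))
  pmax(colSums(res^2), 1e-12)
}

#' BIC covariate ledger
#'
#' For each candidate covariate, fits every region with the base design and
#' with the candidate appended (numeric candidates are median-centered within
#' cell type first, mirroring the normalization of technical metrics "to the
#' median of the cell type"). The per-region BIC improvement is
#' `BIC_base - BIC_extended`; the candidate is included iff the fraction of
#' regions with improvement >= `delta_bic` reaches `min_fraction`. Candidates
#' collinear with the base design add no rank and score zero improvement
#' everywhere. Subject random intercepts are deliberately excluded here: the
#' ledger is a screening heuristic over plain OLS fits.
#'
#' @param norm region x sample normalized matrix.
#' @param sheet a [sample_sheet()] aligned to the matrix columns.
#' @param config a [ledger_config()].
#' @return data.frame (classed `ledger_report`): per candidate `n_improved`,
#'   `n_worse`, `net`, `frac_exceeding`, `included`.
#' @export
bic_ledger <- function(norm, sheet, config) {
  stopifnot(inherits(config, "ledger_config"))
  sheet <- sheet[match(colnames(norm), sheet$sample_id), , drop = FALSE]
  X0 <- base_design(sheet)
  n <- ncol(norm)
  if (n <= ncol(X0) + 1)
    stop("need n_samples > n_parameters", call. = FALSE)
  rss0 <- all_region_rss(norm, X0)
  rank0 <- qr(X0)$rank

  rows <- lapply(config$candidates, function(cand) {
    if (!cand %in% names(sheet))
      stop("candidate '", cand, "' is not a sample-sheet column", call. = FALSE)
    v <- sheet[[cand]]
    if (is.numeric(v)) {
      v <- stats::ave(v, sheet$cell_type, FUN = function(z) z - stats::median(z))
      Xc <- cbind(X0, cand = v)
    } else {
      mm <- stats::model.matrix(~ f, data.frame(f = factor(v)))[, -1, drop = FALSE]
      Xc <- cbind(X0, mm)
    }
    added <- ncol(Xc) - ncol(X0)
    qr_c <- qr(Xc)
    if (qr_c$rank <= rank0) {
      # no added information: extended model == base model
      improvement <- rep(0, nrow(norm))
    } else {
      keep <- qr_c$pivot[seq_len(qr_c$rank)]
      Xc <- Xc[, sort(keep), drop = FALSE]
      added <- ncol(Xc) - ncol(X0)
      rss1 <- all_region_rss(norm, Xc)
      improvement <- n * log(rss0 / rss1) - added * log(n)
    }
    data.frame(candidate = cand,
               n_improved = sum(improvement > 0),
               n_worse = sum(improvement < 0),
               net = sum(improvement > 0) - sum(improvement < 0),
               frac_exceeding = mean(improvement >= config$delta_bic),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$included <- report$frac_exceeding >= config$min_fraction
  class(report) <- c("ledger_report", "data.frame")
  report
}

#' Sensitivity grid over ledger thresholds
#'
#' Re-evaluates the inclusion decision over a grid of `delta_bic` and
#' `min_fraction` values (defaults: the tested grids 2/4/10 and 2%/5%).
#'
#' @param norm,sheet,config as in [bic_ledger()].
#' @param delta_bic_grid,min_fraction_grid numeric grids.
#' @return data.frame with one row per candidate x grid point.
#' @export
ledger_grid <- function(norm, sheet, config,
                        delta_bic_grid = c(2, 4, 10),
                        min_fraction_grid = c(0.02, 0.05)) {
  out <- list()
  for (d in delta_bic_grid) {
    cfg <- config; cfg$delta_bic <- d
    rep_d <- bic_ledger(norm, sheet, cfg)
    for (f in min_fraction_grid) {
      r <- as.data.frame(rep_d)
      r$delta_bic <- d
      r$min_fraction <- f
      r$included <- r$frac_exceeding >= f
      out[[length(out) + 1L]] <- r
    }
  }
  do.call(rbind, out)
}
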