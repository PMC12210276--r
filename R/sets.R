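# Gene-set overlap statistics: Fisher-exact odds ratios, the "rescue"
# classification of stress-responsive genes, and Jaccard redundancy pruning.

#' Overlap odds ratio with Fisher exact p
#'
#' Builds the 2x2 table `a = |A intersect B|`, `b = |A \\ B|`,
#' `c = |B \\ A|`, `d = |universe \\ (A union B)|`; the odds ratio is the
#' sample cross-product `ad / bc` (reported as `Inf` when `bc = 0` and
#' `ad > 0`; no Haldane correction), and the p-value is the two-sided Fisher
#' exact test (hypergeometric tail summation). Symmetric in A and B.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector (nonempty).
#' @return list (classed `overlap_result`): `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_value`.
#' @export
overlap_odds_ratio <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  stray <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(stray))
    stop("gene(s) outside universe: ", paste(stray, collapse = ", "),
         call. = FALSE)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - cc
  or <- if (b * cc == 0) {
    if (a * d > 0) Inf else if (a * d == 0 && b * cc == 0) NaN else 0
  } else a * d / (b * cc)
  if (is.nan(or) && (a == 0 || d == 0)) or <- 0   # degenerate margins
  p <- stats::fisher.test(matrix(c(a, b, cc, d), 2))$p.value
  structure(list(a = a, b = b, c = cc, d = d, odds_ratio = or, p_value = p),
            class = "overlap_result")
}

#' Rescue classification of stress-responsive genes
#'
#' A stress DEG (q < `fdr` in the stress-vs-control table) counts as
#' "rescued" when the rescue contrast moves it significantly (q < `fdr`) in
#' the opposite direction — expression shifted back toward control-like
#' levels. `mode = "sign_only"` drops the significance requirement on the
#' rescue contrast and asks only for sign reversal.
#'
#' @param stress_de,rescue_de `differential_table`-like data.frames with
#'   columns `region` (gene id), `logFC`, `q_value`.
#' @param fdr q-value threshold (default 0.1).
#' @param mode `"significant"` (default) or `"sign_only"`.
#' @return list (classed `rescue_report`): `n_stress_degs`, `n_rescued`,
#'   `fraction_rescued`, plus `up`/`down` strata (by stress direction).
#' @export
rescue_fraction <- function(stress_de, rescue_de, fdr = 0.1,
                            mode = c("significant", "sign_only")) {
  mode <- match.arg(mode)
  for (tab in list(stress_de, rescue_de))
    if (!all(c("region", "logFC", "q_value") %in% names(tab)))
      stop("tables need region, logFC and q_value columns", call. = FALSE)
  shared <- intersect(stress_de$region, rescue_de$region)
  if (!length(shared)) stop("no shared gene identifiers", call. = FALSE)
  s <- stress_de[match(shared, stress_de$region), ]
  r <- rescue_de[match(shared, rescue_de$region), ]
  is_deg <- s$q_value < fdr
  opposite <- sign(r$logFC) == -sign(s$logFC) & s$logFC != 0
  rescued <- is_deg & opposite &
    (if (mode == "significant") r$q_value < fdr else TRUE)
  strata <- function(sel) {
    n <- sum(is_deg & sel)
    k <- sum(rescued & sel)
    list(n_stress_degs = n, n_rescued = k,
         fraction_rescued = if (n > 0) k / n else NA_real_)
  }
  structure(list(
    n_stress_degs = sum(is_deg),
    n_rescued = sum(rescued),
    fraction_rescued = if (sum(is_deg) > 0) sum(rescued) / sum(is_deg)
                       else NA_real_,
    up = strata(s$logFC > 0),
    down = strata(s$logFC < 0),
    fdr = fdr, mode = mode
  ), class = "rescue_report")
}

jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Prune redundant gene sets by Jaccard similarity
#'
#' Iteratively finds the pair with the largest Jaccard index at or above
#' `threshold` and removes the smaller set (ties broken deterministically:
#' the lexicographically later name is removed), until all pairwise Jaccard
#' indices fall below the threshold. Idempotent.
#'
#' @param collection a [gene_set_collection()].
#' @param threshold Jaccard cutoff in `(0, 1]` (default 0.5).
#' @return pruned [gene_set_collection()]; attribute `removed` lists dropped
#'   set names in removal order.
#' @export
jaccard_prune <- function(collection, threshold = 0.5) {
  stopifnot(inherits(collection, "gene_set_collection"))
  check_fraction(threshold, "threshold", lo = 1e-12)
  sets <- collection$sets
  removed <- character(0)
  repeat {
    nms <- names(sets)
    if (length(nms) < 2L) break
    best <- NULL; best_j <- -1
    for (i in seq_along(nms)[-length(nms)]) {
      for (j in (i + 1L):length(nms)) {
        jc <- jaccard_index(sets[[i]], sets[[j]])
        if (jc > best_j) { best_j <- jc; best <- c(i, j) }
      }
    }
    if (best_j < threshold) break
    i <- best[1]; j <- best[2]
    li <- length(sets[[i]]); lj <- length(sets[[j]])
    drop_idx <- if (li < lj) i else if (lj < li) j
                else if (nms[i] < nms[j]) j else i   # tie: later name goes
    removed <- c(removed, nms[drop_idx])
    sets[[drop_idx]] <- NULL
  }
  out <- gene_set_collection(sets, collection$universe)
  attr(out, "removed") <- removed
  out
}
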