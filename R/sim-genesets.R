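#' Simulate overlapping gene sets with target Jaccard indices
#'
#' Builds `n_sets` gene sets over a universe of `universe_size` genes such
#' that requested pairwise Jaccard indices are realized within ±0.05 where
#' feasible. Each entry of `overlap_profile` is a list/vector
#' `(i, j, jaccard)` constraining the pair of set indices `i < j`. A set may
#' be constrained against at most one earlier set (profiles forming a forest);
#' richer profiles are rejected as infeasible, as are overlaps that cannot be
#' realized with the available set sizes.
#'
#' @param n_sets number of sets.
#' @param universe_size number of genes in the universe.
#' @param overlap_profile list of `(i, j, jaccard)` constraints with
#'   `jaccard` in `[0, 1]`.
#' @param set_size size of each set (default `max(5, universe_size %/% 10)`).
#' @param seed integer seed.
#' @return a [gene_set_collection()].
#' @export
simulate_gene_sets <- function(n_sets, universe_size, overlap_profile = list(),
                               set_size = NULL, seed = 1L) {
  check_count(n_sets, "n_sets"); check_count(universe_size, "universe_size")
  set.seed(check_count(seed, "seed", min = 0L))
  if (is.null(set_size)) set_size <- max(5L, universe_size %/% 10L)
  sizes <- rep(as.integer(set_size), n_sets)
  universe <- sprintf("gene%05d", seq_len(universe_size))

  prof <- lapply(overlap_profile, function(p) {
    p <- unlist(p)
    if (length(p) != 3L) stop_field("overlap_profile", "entries must be (i, j, jaccard)")
    if (p[1] >= p[2]) p[1:2] <- p[2:1]
    check_fraction(p[3], "overlap_profile jaccard")
    p
  })
  constrained_by <- rep(NA_integer_, n_sets)
  target_j <- rep(NA_real_, n_sets)
  for (p in prof) {
    j <- as.integer(p[2])
    if (!is.na(constrained_by[j]))
      stop("infeasible overlap_profile: set ", j,
           " constrained against more than one earlier set", call. = FALSE)
    constrained_by[j] <- as.integer(p[1])
    target_j[j] <- p[3]
  }

  sets <- vector("list", n_sets)
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  for (k in seq_len(n_sets)) {
    if (is.na(constrained_by[k])) {
      sets[[k]] <- sample(universe, sizes[k])
    } else {
      a <- sets[[constrained_by[k]]]
      J <- target_j[k]
      sa <- length(a); sb <- sizes[k]
      # J = o / (sa + sb - o)  =>  o = J (sa + sb) / (1 + J)
      o <- round(J * (sa + sb) / (1 + J))
      if (o > min(sa, sb) || (sb - o) > (universe_size - sa))
        stop("infeasible overlap_profile: cannot realize Jaccard ", J,
             " between sets of sizes ", sa, " and ", sb, call. = FALSE)
      realized <- o / (sa + sb - o)
      if (abs(realized - J) > 0.05)
        stop("infeasible overlap_profile: closest realizable Jaccard is ",
             signif(realized, 3), " for target ", J, call. = FALSE)
      shared <- sample(a, o)
      fresh <- sample(setdiff(universe, a), sb - o)
      sets[[k]] <- c(shared, fresh)
    }
  }
  gene_set_collection(sets, universe)
}
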