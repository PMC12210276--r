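#' Simulate genotype calls with sex chromosomes and duplicate pairs
#'
#' Emulates joint genotype calls across a cohort for identity QC: autosomal
#' and chrX variants in Hardy-Weinberg proportions, hemizygous male chrX
#' (non-PAR) calls coded 0/2 so male heterozygosity is exactly zero, chrY
#' calls missing in females, a small fraction of chrX PAR variants that behave
#' autosomally, and optional duplicate sample pairs sharing >= 99% of calls.
#' Autosomal minor allele frequencies are drawn in `[0.05, 0.5]` so downstream
#' MAF filters (5% and 25%) retain nonempty sets.
#'
#' @param n_subjects number of samples.
#' @param n_variants total variant count; split roughly 60% autosomal, 20%
#'   chrX non-PAR, 5% chrX PAR, 15% chrY non-PAR; each non-PAR class must end
#'   up with >= 20 variants.
#' @param sex_by_subject named character vector `male`/`female` per subject id.
#' @param duplicate_pairs list of length-2 character vectors of subject ids;
#'   the second member's calls are copied from the first with 0.2% discordance.
#' @param missing_rate fraction of calls set missing at random (default 1%).
#' @param seed integer seed.
#' @return a [genotype_table()].
#' @export
simulate_genotypes <- function(n_subjects, n_variants, sex_by_subject,
                               duplicate_pairs = list(), missing_rate = 0.01,
                               seed = 1L) {
  if (length(sex_by_subject) == 0)
    stop_field("sex_by_subject", "must be a nonempty named vector")
  if (is.null(names(sex_by_subject)))
    stop_field("sex_by_subject", "must be named by subject id")
  check_count(n_subjects, "n_subjects")
  if (length(sex_by_subject) != n_subjects)
    stop_field("sex_by_subject", "length must equal n_subjects")
  check_fraction(missing_rate, "missing_rate", hi = 0.5)
  set.seed(check_count(seed, "seed", min = 0L))

  n_auto <- round(0.60 * n_variants)
  n_x <- round(0.20 * n_variants)
  n_par <- round(0.05 * n_variants)
  n_y <- n_variants - n_auto - n_x - n_par
  if (min(n_auto, n_x, n_y) < 20L)
    stop_field("n_variants",
               "too few variants: need >= 20 per chromosome class (autosome, chrX non-PAR, chrY non-PAR)")

  chrom <- c(rep("chr1", n_auto), rep("chrX", n_x + n_par), rep("chrY", n_y))
  is_par <- c(rep(FALSE, n_auto), rep(FALSE, n_x), rep(TRUE, n_par),
              rep(FALSE, n_y))
  maf <- stats::runif(n_variants, 0.05, 0.5)
  pos <- seq_len(n_variants) * 1000L

  subjects <- names(sex_by_subject)
  male <- sex_by_subject == "male"
  calls <- matrix(NA_integer_, n_variants, n_subjects,
                  dimnames = list(NULL, subjects))

  diploid <- function(p, n) stats::rbinom(n, 2L, p)
  for (s in seq_len(n_subjects)) {
    g <- integer(n_variants)
    auto_like <- chrom == "chr1" | is_par
    g[auto_like] <- diploid(maf[auto_like], sum(auto_like))
    xnp <- chrom == "chrX" & !is_par
    if (male[s]) {
      g[xnp] <- 2L * stats::rbinom(sum(xnp), 1L, maf[xnp])   # hemizygous
      ynp <- chrom == "chrY"
      g[ynp] <- 2L * stats::rbinom(sum(ynp), 1L, maf[ynp])
    } else {
      g[xnp] <- diploid(maf[xnp], sum(xnp))
      g[chrom == "chrY"] <- NA_integer_
    }
    calls[, s] <- g
  }

  # random missingness (chrY female missingness already structural)
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(length(calls)) < missing_rate, nrow(calls))
    calls[miss] <- NA_integer_
  }

  for (pr in duplicate_pairs) {
    if (length(pr) != 2L || !all(pr %in% subjects))
      stop_field("duplicate_pairs", "entries must be pairs of known subject ids")
    src <- calls[, pr[1]]
    flip <- which(stats::runif(n_variants) < 0.002 & !is.na(src))
    dup <- src
    dup[flip] <- (src[flip] + 1L) %% 3L
    calls[, pr[2]] <- dup
  }

  genotype_table(
    variants = data.frame(chrom = chrom, pos = pos, maf = maf, is_par = is_par,
                          stringsAsFactors = FALSE),
    calls = calls
  )
}
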