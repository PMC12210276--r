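#' Specification for the ATAC-seq count simulator
#'
#' Describes a synthetic case/control cohort: paired libraries (one per cell
#' type) for each subject, negative-binomial read counts over genomic regions,
#' a planted subset of regions carrying a cell-type-specific diagnosis effect,
#' optional sample-level nuisance covariates with planted region effects, and
#' sex-linked marker regions (chrX female markers, chrY male regions) used by
#' the sex-inference QC.
#'
#' @param n_subjects number of subjects; each contributes one library per cell
#'   type.
#' @param groups fraction of subjects that are cases, in `[0, 1]`.
#' @param cell_types number of cell types (paired libraries per subject).
#' @param n_regions number of genomic regions (peaks / OCRs).
#' @param frac_differential fraction of regions carrying the planted
#'   case/control effect (applied in the first cell type only).
#' @param effect_lfc log2 fold-change magnitude of the planted effect; the
#'   sign is drawn per region.
#' @param dispersion negative-binomial dispersion (> 0), constant across
#'   regions; counts have variance `mu + dispersion * mu^2`.
#' @param library_size_range length-2 positive vector; library sizes are drawn
#'   uniformly in this range.
#' @param covariates optional list of planted nuisance covariates; each element
#'   is a list with `name`, `effect_lfc` (log2 change per unit of the
#'   standard-normal covariate) and `frac_affected_regions`.
#' @param sex_region_fractions named numeric vector with elements
#'   `chrx_marker`, `chry` and `autosomal` summing to 1: fractions of regions
#'   tagged as female-marker chrX regions, chrY regions, and autosomal.
#' @param frac_female fraction of subjects simulated as female.
#' @param seed integer seed; fixes the output bit-for-bit.
#' @return a validated `atac_sim_spec` list.
#' @export
atac_sim_spec <- function(n_subjects = 39, groups = 20 / 39, cell_types = 2,
                          n_regions = 1000, frac_differential = 0.05,
                          effect_lfc = 1, dispersion = 0.2,
                          library_size_range = c(5e5, 2e6),
                          covariates = list(),
                          sex_region_fractions = c(chrx_marker = 0.01,
                                                   chry = 0.01,
                                                   autosomal = 0.98),
                          frac_female = 0.5,
                          seed = 1L) {
  spec <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    groups = check_fraction(groups, "groups"),
    cell_types = check_count(cell_types, "cell_types"),
    n_regions = check_count(n_regions, "n_regions"),
    frac_differential = check_fraction(frac_differential, "frac_differential"),
    effect_lfc = check_fraction(abs(effect_lfc), "effect_lfc", hi = Inf),
    dispersion = check_positive(dispersion, "dispersion"),
    library_size_range = library_size_range,
    covariates = covariates,
    sex_region_fractions = sex_region_fractions,
    frac_female = check_fraction(frac_female, "frac_female"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(library_size_range) || length(library_size_range) != 2L ||
      any(library_size_range <= 0) ||
      library_size_range[1] > library_size_range[2])
    stop_field("library_size_range", "must be an increasing pair of positive numbers")
  if (!all(c("chrx_marker", "chry", "autosomal") %in% names(sex_region_fractions)))
    stop_field("sex_region_fractions", "needs chrx_marker, chry and autosomal entries")
  if (any(sex_region_fractions < 0) || abs(sum(sex_region_fractions) - 1) > 1e-8)
    stop_field("sex_region_fractions", "fractions must be nonnegative and sum to 1")
  for (cv in covariates) {
    if (is.null(cv$name) || is.null(cv$effect_lfc) || is.null(cv$frac_affected_regions))
      stop_field("covariates", "each entry needs name, effect_lfc, frac_affected_regions")
    check_fraction(cv$frac_affected_regions, "covariates$frac_affected_regions")
  }
  class(spec) <- "atac_sim_spec"
  spec
}

#' Simulate an ATAC-seq count matrix with planted ground truth
#'
#' Counts are negative-binomial with mean
#' `library_size * region_weight * 2^(design effects)`. Region weights are
#' log-normal and normalized to sum to one, so CPM filtering has nontrivial
#' behaviour. Exactly `floor(frac_differential * n_regions)` regions carry the
#' case/control effect, restricted to the first cell type. Female-marker chrX
#' regions are strongly depleted in males, chrY regions depleted in females.
#'
#' @param spec an [atac_sim_spec()].
#' @return list with `counts` (a [region_count_matrix()]), `sheet` (a
#'   [sample_sheet()]) and `truth` (planted labels: `differential_regions`,
#'   `informative_covariates`, `sex_by_sample`, `sex_by_subject`).
#' @export
simulate_atac_counts <- function(spec) {
  if (!inherits(spec, "atac_sim_spec")) spec <- do.call(atac_sim_spec, spec)
  set.seed(spec$seed)
  ns <- spec$n_subjects; nct <- spec$cell_types; nr <- spec$n_regions
  subjects <- sprintf("subj%02d", seq_len(ns))
  n_cases <- round(spec$groups * ns)
  diagnosis <- rep("control", ns)
  if (n_cases > 0) diagnosis[seq_len(n_cases)] <- "case"
  n_female <- round(spec$frac_female * ns)
  sex <- rep("male", ns)
  if (n_female > 0) sex[sample.int(ns, n_female)] <- "female"

  cell_types <- sprintf("celltype%d", seq_len(nct))
  sheet <- data.frame(
    sample_id = as.vector(outer(subjects, cell_types, paste, sep = "_")),
    subject_id = rep(subjects, times = nct),
    cell_type = rep(cell_types, each = ns),
    diagnosis = rep(diagnosis, times = nct),
    sex = rep(sex, times = nct),
    stringsAsFactors = FALSE
  )
  nsamp <- nrow(sheet)

  # region annotation: chrX female markers first, then chrY, then autosomes
  n_x <- round(spec$sex_region_fractions[["chrx_marker"]] * nr)
  n_y <- round(spec$sex_region_fractions[["chry"]] * nr)
  chrom <- c(rep("chrX", n_x), rep("chrY", n_y), rep("chr1", nr - n_x - n_y))
  starts <- seq(0L, by = 1000L, length.out = nr)
  regions <- data.frame(chrom = chrom, start = starts, end = starts + 500L,
                        id = sprintf("region%05d", seq_len(nr)),
                        stringsAsFactors = FALSE)

  w <- exp(stats::rnorm(nr, meanlog_region_weight(nr), 1.0))
  w <- w / sum(w)

  lib <- round(stats::runif(nsamp, spec$library_size_range[1],
                            spec$library_size_range[2]))

  n_diff <- floor(spec$frac_differential * nr)
  auto_idx <- which(chrom == "chr1")
  diff_idx <- if (n_diff > 0) auto_idx[seq_len(min(n_diff, length(auto_idx)))] else integer(0)
  diff_sign <- sample(c(-1, 1), length(diff_idx), replace = TRUE)

  lfc <- matrix(0, nr, nsamp)  # log2 effect per region x sample
  is_case <- sheet$diagnosis == "case"
  in_ct1 <- sheet$cell_type == cell_types[1]
  if (length(diff_idx))
    lfc[diff_idx, is_case & in_ct1] <- lfc[diff_idx, is_case & in_ct1] +
      diff_sign * spec$effect_lfc

  # sex-linked regions
  is_male <- sheet$sex == "male"
  if (n_x > 0) lfc[seq_len(n_x), is_male] <- lfc[seq_len(n_x), is_male] - 3
  if (n_y > 0) lfc[n_x + seq_len(n_y), !is_male] <- lfc[n_x + seq_len(n_y), !is_male] - 5

  cov_cols <- list()
  informative <- character(0)
  for (cv in spec$covariates) {
    z <- stats::rnorm(ns)              # subject-level covariate
    zs <- rep(z, times = nct)
    n_aff <- floor(cv$frac_affected_regions * nr)
    if (n_aff > 0 && abs(cv$effect_lfc) > 0) {
      aff <- sample(auto_idx, min(n_aff, length(auto_idx)))
      lfc[aff, ] <- lfc[aff, ] + outer(rep(cv$effect_lfc, length(aff)), zs)
      informative <- c(informative, cv$name)
    }
    cov_cols[[cv$name]] <- zs
  }
  for (nm in names(cov_cols)) sheet[[nm]] <- cov_cols[[nm]]

  mu <- (w %o% as.numeric(lib)) * 2^lfc
  counts <- matrix(stats::rnbinom(nr * nsamp, mu = mu, size = 1 / spec$dispersion),
                   nr, nsamp, dimnames = list(regions$id, sheet$sample_id))

  truth <- list(
    differential_regions = regions$id[diff_idx],
    differential_sign = stats::setNames(diff_sign, regions$id[diff_idx]),
    informative_covariates = informative,
    sex_by_subject = stats::setNames(sex, subjects),
    sex_by_sample = stats::setNames(sheet$sex, sheet$sample_id),
    chrx_marker_regions = regions$id[seq_len(n_x)],
    chry_regions = regions$id[n_x + seq_len(n_y)]
  )
  list(counts = region_count_matrix(regions, counts),
       sheet = sample_sheet(sheet),
       truth = truth)
}

# meanlog chosen so a typical region weight ~ 1/n_regions before normalization
meanlog_region_weight <- function(n_regions) -log(n_regions)
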