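# Sample-identity and library-quality QC: genetic sex inference from three
# metrics, genotype concordance between libraries, PBC and FRiP.

#' Chromosome-X heterozygosity rate
#'
#' Fraction of heterozygous calls among nonmissing chrX, non-pseudoautosomal
#' variants with MAF >= `maf_min` (default 5%). Near-zero in males
#' (hemizygous); elevated values in an annotated male suggest contamination or
#' a sample swap.
#'
#' @param gt a [genotype_table()].
#' @param sample sample id.
#' @param maf_min MAF filter (default 0.05).
#' @param chrx chromosome name (default `"chrX"`).
#' @return fraction in `[0, 1]`.
#' @export
chrx_het_rate <- function(gt, sample, maf_min = 0.05, chrx = "chrX") {
  stopifnot(inherits(gt, "genotype_table"))
  j <- match(sample, gt$samples)
  if (is.na(j)) stop("unknown sample: ", sample, call. = FALSE)
  elig <- gt$variants$chrom == chrx & !gt$variants$is_par &
    gt$variants$maf >= maf_min
  calls <- gt$calls[elig, j]
  calls <- calls[!is.na(calls)]
  if (!length(calls))
    stop("no eligible chrX non-PAR variant with MAF >= ", maf_min,
         " for sample ", sample, call. = FALSE)
  mean(calls == 1L)
}

#' Summed CPM over marker regions
#'
#' Per-sample sum of CPM over a set of marker regions — used with regions
#' adjacent to female-specific transcripts (XIST/FIRRE-like) and, separately,
#' with chrY non-PAR regions.
#'
#' @param x a [region_count_matrix()].
#' @param marker_region_ids region ids (must all be present).
#' @return named numeric vector (per-sample CPM sum).
#' @export
marker_region_cpm <- function(x, marker_region_ids) {
  missing <- setdiff(marker_region_ids, x$regions$id)
  if (length(missing))
    stop("unknown region id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cpm <- cpm_transform(x)
  colSums(cpm[marker_region_ids, , drop = FALSE])
}

#' Infer genetic sex from three metrics
#'
#' Majority vote of three binarized metrics per sample: high chrX
#' heterozygosity votes female, high female-marker CPM votes female, high chrY
#' CPM votes male. Binarization thresholds default to a deterministic
#' two-means split of each metric across samples; supply `thresholds` to
#' override. Samples whose metrics cannot be split (all equal) are
#' `ambiguous`. A `mismatch_flag` marks disagreement with the annotated sex —
#' such samples are exclusion candidates.
#'
#' @param chrx_het named numeric vector (per sample).
#' @param female_marker_cpm named numeric vector.
#' @param chry_cpm named numeric vector.
#' @param annotated_sex named character vector (`male`/`female`/`unknown`).
#' @param thresholds optional list with elements `chrx_het`,
#'   `female_marker_cpm`, `chry_cpm`.
#' @return data.frame: sample, the three metrics, `inferred_sex`
#'   (`male`/`female`/`ambiguous`), `mismatch_flag`.
#' @export
infer_sex <- function(chrx_het, female_marker_cpm, chry_cpm, annotated_sex,
                      thresholds = NULL) {
  samples <- names(chrx_het)
  stopifnot(!is.null(samples),
            identical(samples, names(female_marker_cpm)),
            identical(samples, names(chry_cpm)))
  thr <- list(
    chrx_het = thresholds$chrx_het %||% split_two_means(chrx_het),
    female_marker_cpm = thresholds$female_marker_cpm %||%
      split_two_means(female_marker_cpm),
    chry_cpm = thresholds$chry_cpm %||% split_two_means(chry_cpm)
  )
  vote <- function(metric, cut, female_if_high) {
    if (is.na(cut)) return(rep(NA, length(metric)))
    high <- metric > cut
    if (female_if_high) high else !high
  }
  votes <- cbind(
    vote(chrx_het, thr$chrx_het, female_if_high = TRUE),
    vote(female_marker_cpm, thr$female_marker_cpm, female_if_high = TRUE),
    vote(chry_cpm, thr$chry_cpm, female_if_high = FALSE)
  )
  n_female <- rowSums(votes, na.rm = TRUE)
  n_avail <- rowSums(!is.na(votes))
  inferred <- ifelse(n_avail == 0, "ambiguous",
                     ifelse(n_female > n_avail / 2, "female",
                            ifelse(n_female < n_avail / 2, "male",
                                   "ambiguous")))
  ann <- annotated_sex[samples]
  mismatch <- !is.na(ann) & ann %in% c("male", "female") &
    inferred != "ambiguous" & inferred != ann
  data.frame(sample = samples,
             chrx_het = as.numeric(chrx_het),
             female_marker_cpm = as.numeric(female_marker_cpm),
             chry_cpm = as.numeric(chry_cpm),
             annotated_sex = as.character(ann),
             inferred_sex = inferred,
             mismatch_flag = mismatch,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genotype concordance between two samples
#'
#' Fraction of matching calls among variants nonmissing in both samples,
#' restricted to MAF >= `maf_min` (default 25%, a deliberately common-variant
#' filter so random matches are informative). Libraries from the same subject
#' should score near 1.
#'
#' @param gt a [genotype_table()].
#' @param sample_a,sample_b sample ids.
#' @param maf_min MAF filter (default 0.25).
#' @return fraction in `[0, 1]`.
#' @export
genotype_concordance <- function(gt, sample_a, sample_b, maf_min = 0.25) {
  stopifnot(inherits(gt, "genotype_table"))
  ja <- match(sample_a, gt$samples); jb <- match(sample_b, gt$samples)
  if (is.na(ja) || is.na(jb))
    stop("unknown sample id(s)", call. = FALSE)
  elig <- gt$variants$maf >= maf_min
  a <- gt$calls[elig, ja]; b <- gt$calls[elig, jb]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop("no shared nonmissing variant with MAF >= ", maf_min, call. = FALSE)
  mean(a[ok] == b[ok])
}

#' PCR bottleneck coefficient
#'
#' `PBC = nonredundant / uniquely_mapped`, an approximate library-complexity
#' measure.
#'
#' @param uniquely_mapped uniquely mapped read count (> 0).
#' @param nonredundant nonredundant uniquely mapped read count.
#' @return fraction in `[0, 1]`.
#' @export
pbc <- function(uniquely_mapped, nonredundant) {
  if (uniquely_mapped <= 0)
    stop("uniquely_mapped must be > 0", call. = FALSE)
  if (nonredundant < 0 || nonredundant > uniquely_mapped)
    stop("need 0 <= nonredundant <= uniquely_mapped", call. = FALSE)
  nonredundant / uniquely_mapped
}

#' Fraction of reads in peaks
#'
#' @param reads_in_peaks reads overlapping called peaks.
#' @param total_reads total reads (> 0).
#' @return fraction in `[0, 1]`.
#' @export
frip <- function(reads_in_peaks, total_reads) {
  if (total_reads <= 0) stop("total_reads must be > 0", call. = FALSE)
  if (reads_in_peaks < 0 || reads_in_peaks > total_reads)
    stop("need 0 <= reads_in_peaks <= total_reads", call. = FALSE)
  reads_in_peaks / total_reads
}
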