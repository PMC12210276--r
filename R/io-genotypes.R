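# Minimal VCF v4.2 support: GT-only writer (plain text) and a vcfR-backed
# reader. Calls are coded by ALT allele count; "./." (and half-missing calls)
# are missing and excluded from MAF and heterozygosity denominators. Phased
# "|" and unphased "/" separators are treated identically.

#' Write a genotype table as a minimal GT-only VCF v4.2
#'
#' @param gt a [genotype_table()].
#' @param path output path (plain text `.vcf`).
#' @export
write_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  gt_str <- matrix("./.", nrow(gt$calls), ncol(gt$calls))
  gt_str[gt$calls == 0L] <- "0/0"
  gt_str[gt$calls == 1L] <- "0/1"
  gt_str[gt$calls == 2L] <- "1/1"
  body <- cbind(gt$variants$chrom, gt$variants$pos,
                sprintf("var%05d", seq_len(nrow(gt$calls))), "A", "G", ".",
                "PASS",
                sprintf("MAF=%.6g;PAR=%d", gt$variants$maf,
                        as.integer(gt$variants$is_par)),
                "GT", gt_str)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=PAR,Number=1,Type=Integer,Description=\"1 if inside a pseudoautosomal region\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples), collapse = "\t"))
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(gt)
}

#' Load genotype calls from a VCF
#'
#' Reads a VCF (via `vcfR`), codes calls as 0/1/2 ALT-allele counts with `NA`
#' for missing, flags pseudoautosomal variants from the supplied intervals (or
#' from a `PAR` INFO tag if present), and computes MAF from nonmissing calls
#' when no `MAF` INFO tag is present.
#'
#' @param vcf_path VCF file (must carry a GT FORMAT field).
#' @param par_intervals optional data.frame `chrom`, `start`, `end` (1-based,
#'   inclusive) of pseudoautosomal intervals.
#' @return a [genotype_table()].
#' @export
load_genotypes <- function(vcf_path, par_intervals = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (!"GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !grepl("GT", v@gt[1, "FORMAT"]))
    stop("VCF has no GT field", call. = FALSE)
  gt_str <- vcfR::extract.gt(v, element = "GT")
  code1 <- function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".") || !all(al %in% c("0", "1"))) return(NA_integer_)
    sum(al == "1")
  }
  calls <- apply(gt_str, c(1, 2), code1)
  malformed <- apply(gt_str, 1, function(r) {
    any(!is.na(r) & !grepl("^[01.]([/|][01.])?$", r))
  })
  if (any(malformed)) {
    warning(sum(malformed), " record(s) with malformed GT skipped")
    calls <- calls[!malformed, , drop = FALSE]
    v@fix <- v@fix[!malformed, , drop = FALSE]
  }
  if (nrow(calls) == 0L) stop("all VCF records skipped", call. = FALSE)

  chrom <- as.character(v@fix[, "CHROM"])
  pos <- as.integer(v@fix[, "POS"])
  info <- as.character(v@fix[, "INFO"])

  maf_tag <- suppressWarnings(
    as.numeric(sub(".*MAF=([0-9.eE+-]+).*", "\\1",
                   ifelse(grepl("MAF=", info), info, NA))))
  af <- rowMeans(calls, na.rm = TRUE) / 2
  maf_emp <- pmin(af, 1 - af)
  maf <- ifelse(is.na(maf_tag), maf_emp, maf_tag)

  if (!is.null(par_intervals)) {
    is_par <- vapply(seq_along(chrom), function(i) {
      any(par_intervals$chrom == chrom[i] &
            par_intervals$start <= pos[i] & pos[i] <= par_intervals$end)
    }, logical(1))
  } else if (any(grepl("PAR=", info))) {
    is_par <- grepl("PAR=1", info)
  } else {
    is_par <- rep(FALSE, length(chrom))
  }

  genotype_table(
    variants = data.frame(chrom = chrom, pos = pos, maf = maf, is_par = is_par,
                          stringsAsFactors = FALSE),
    calls = calls
  )
}
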