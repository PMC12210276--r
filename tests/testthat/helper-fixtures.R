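# Shared fixtures, built in code at test time.

tiny_counts <- function(counts, chrom = "chr1") {
  nr <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("r%02d", seq_len(nr))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  regions <- data.frame(chrom = chrom,
                        start = seq(0L, by = 100L, length.out = nr),
                        end = seq(50L, by = 100L, length.out = nr),
                        id = rownames(counts), stringsAsFactors = FALSE)
  region_count_matrix(regions, counts)
}

toy_sheet <- function(n_subjects = 10, cell_types = c("celltype1", "celltype2"),
                      frac_case = 0.5) {
  subj <- sprintf("subj%02d", seq_len(n_subjects))
  diag <- rep(c("case", "control"),
              c(round(frac_case * n_subjects),
                n_subjects - round(frac_case * n_subjects)))
  sex <- rep(c("male", "female"), length.out = n_subjects)
  df <- expand.grid(subject_id = subj, cell_type = cell_types,
                    stringsAsFactors = FALSE)
  df$sample_id <- paste(df$subject_id, df$cell_type, sep = "_")
  df$diagnosis <- diag[match(df$subject_id, subj)]
  df$sex <- sex[match(df$subject_id, subj)]
  sample_sheet(df[, c("sample_id", "subject_id", "cell_type", "diagnosis", "sex")])
}

# independent brute-force TMM oracle (double-trimmed weighted mean of M-values)
oracle_tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                            trim_m = 0.30, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  p_o <- obs / lib_obs; p_r <- ref / lib_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(M) & is.finite(A) & A > -1e10
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# brute-force two-sided Fisher exact p over all tables with fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# sort-and-scan BH oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n); q[o] <- pmin(q_sorted, 1)
  q
}
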