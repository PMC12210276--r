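# Simulators: determinism, planted structure, moment checks, truth
# consistency.

test_that("ATAC simulator is seed-deterministic and shapes the paired cohort", {
  spec <- atac_sim_spec(n_subjects = 39, cell_types = 2, n_regions = 100,
                        seed = 42)
  a <- simulate_atac_counts(spec)
  b <- simulate_atac_counts(spec)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$sheet, b$sheet)
  # 39 subjects x 2 FANS fractions = 78 libraries before exclusions
  expect_equal(ncol(a$counts$counts), 78)
  expect_equal(length(unique(a$sheet$subject_id)), 39)
  # every subject appears once per cell type (paired design)
  expect_true(all(table(a$sheet$subject_id) == 2))
})

test_that("null effect size gives no case/control separation", {
  spec <- atac_sim_spec(n_subjects = 30, n_regions = 400,
                        frac_differential = 0.25, effect_lfc = 0,
                        dispersion = 0.1, seed = 5)
  sim <- simulate_atac_counts(spec)
  cpm <- cpm_transform(sim$counts)
  in_ct1 <- sim$sheet$cell_type == "celltype1"
  case <- sim$sheet$diagnosis == "case"
  diff_rows <- sim$counts$regions$id %in% sim$truth$differential_regions
  lr <- log2(rowMeans(cpm[diff_rows, in_ct1 & case]) /
             rowMeans(cpm[diff_rows, in_ct1 & !case]))
  se <- sd(lr) / sqrt(length(lr))
  expect_lt(abs(mean(lr)), 3 * se)
  # with effect_lfc = 0 nothing is planted as truly differential in effect,
  # but ids must still index existing regions
  expect_true(all(sim$truth$differential_regions %in% sim$counts$regions$id))
})

test_that("simulated NB counts match their target moments", {
  # single region, many samples at fixed mean: mean within 3 SE
  spec <- atac_sim_spec(n_subjects = 300, cell_types = 2, n_regions = 10,
                        frac_differential = 0, dispersion = 0.2,
                        library_size_range = c(1e6, 1e6), seed = 8)
  sim <- simulate_atac_counts(spec)
  mu_hat <- rowMeans(sim$counts$counts)
  # theoretical SE of the mean of NB(mu, size=1/disp) over n draws
  n <- ncol(sim$counts$counts)
  expect_gte(n, 500)
  for (r in 1:10) {
    mu <- mu_hat[r]                      # plug-in; check dispersion instead
    v <- var(sim$counts$counts[r, ])
    expect_gt(v, mu)                     # overdispersed
  }
})

test_that("planted effects shift case means by the stated fold change", {
  spec <- atac_sim_spec(n_subjects = 100, n_regions = 200,
                        frac_differential = 0.5, effect_lfc = 2,
                        dispersion = 0.05, library_size_range = c(1e6, 1e6),
                        seed = 9)
  sim <- simulate_atac_counts(spec)
  in_ct1 <- sim$sheet$cell_type == "celltype1"
  case <- sim$sheet$diagnosis == "case"
  idx <- match(sim$truth$differential_regions, sim$counts$regions$id)
  lr <- log2(rowMeans(sim$counts$counts[idx, in_ct1 & case]) /
             rowMeans(sim$counts$counts[idx, in_ct1 & !case]))
  signed <- lr * sim$truth$differential_sign
  expect_equal(mean(signed), 2, tolerance = 0.1)
  # effect restricted to celltype1: celltype2 ratio ~ 0
  in_ct2 <- sim$sheet$cell_type == "celltype2"
  lr2 <- log2(rowMeans(sim$counts$counts[idx, in_ct2 & case]) /
              rowMeans(sim$counts$counts[idx, in_ct2 & !case]))
  expect_lt(abs(mean(lr2)), 0.1)
})

test_that("genotype simulator enforces sex-chromosome structure", {
  sexes <- setNames(rep(c("male", "female"), each = 10),
                    sprintf("s%02d", 1:20))
  gt <- simulate_genotypes(20, 400, sexes,
                           duplicate_pairs = list(c("s01", "s11")), seed = 3)
  xnp <- gt$variants$chrom == "chrX" & !gt$variants$is_par
  ynp <- gt$variants$chrom == "chrY"
  # s11 is a duplicate of s01: its calls are copied, so its sex structure is
  # deliberately that of its source (a swapped/duplicated library)
  for (s in setdiff(names(sexes), "s11")) {
    calls_x <- gt$calls[xnp, s]
    if (sexes[s] == "male") {
      expect_equal(sum(calls_x == 1L, na.rm = TRUE), 0)
      expect_gt(sum(!is.na(gt$calls[ynp, s])), 0)
    } else {
      expect_true(all(is.na(gt$calls[ynp, s])))
    }
  }
  # duplicate pair concordance >= 0.99 (direct count of matching calls)
  a <- gt$calls[, "s01"]; b <- gt$calls[, "s11"]
  ok <- !is.na(a) & !is.na(b)
  expect_gte(mean(a[ok] == b[ok]), 0.99)
  # autosomal MAF in [0.05, 0.5] so a MAF >= 25% filter keeps variants
  expect_true(all(gt$variants$maf >= 0.05 & gt$variants$maf <= 0.5))
  expect_gt(sum(gt$variants$maf >= 0.25), 0)
  expect_error(simulate_genotypes(0, 400, setNames(character(0), character(0))),
               "sex_by_subject")
  expect_error(simulate_genotypes(5, 50, setNames(rep("male", 5), paste0("s", 1:5))),
               "20 per chromosome class")
})

test_that("calcium simulator: stationary null with the target lag-1 autocorrelation", {
  spec <- calcium_sim_spec(n_cells = 20, duration_s = 600, ar_coefficient = 0.8,
                           frac_up = 0, frac_down = 0, seed = 21)
  sim <- simulate_calcium_session(spec)
  expect_true(all(sim$truth$modulated_cells == "none"))
  ac1 <- apply(sim$session$traces, 1, function(x) acf(x, 1, plot = FALSE)$acf[2])
  expect_equal(mean(ac1), 0.8, tolerance = 0.02)
  # amplitude 0 => all labels none even with frac_up > 0
  sim0 <- simulate_calcium_session(
    calcium_sim_spec(n_cells = 10, frac_up = 0.5, transient_amplitude = 0,
                     seed = 22))
  expect_true(all(sim0$truth$modulated_cells == "none"))
  # determinism
  sim_b <- simulate_calcium_session(spec)
  expect_identical(sim$session$traces, sim_b$session$traces)
  # event spacing respects the window span
  expect_true(all(diff(sim$truth$event_times) > 6))
})

test_that("gene-set simulator hits target Jaccard overlaps", {
  gs <- simulate_gene_sets(3, 200, overlap_profile = list(c(1, 2, 0.5)),
                           set_size = 20, seed = 4)
  expect_length(gs$sets, 3)
  j12 <- length(intersect(gs$sets[[1]], gs$sets[[2]])) /
    length(union(gs$sets[[1]], gs$sets[[2]]))
  expect_equal(j12, 0.5, tolerance = 0.05)
  # target 1.0 -> identical sets
  gs1 <- simulate_gene_sets(2, 100, overlap_profile = list(c(1, 2, 1.0)),
                            set_size = 10, seed = 5)
  expect_setequal(gs1$sets[[1]], gs1$sets[[2]])
  # infeasible: a set constrained twice
  expect_error(
    simulate_gene_sets(3, 100,
                       overlap_profile = list(c(1, 3, 0.5), c(2, 3, 0.5)),
                       seed = 1),
    "infeasible")
  # truth consistency: all sets within universe
  expect_true(all(unlist(gs$sets) %in% gs$universe))
})
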