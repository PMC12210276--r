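# Validation of the differential region set: (i) label-permutation
# calibration -- diagnosis permuted at subject level so both of a subject's
# libraries flip together, the whole differential pipeline rerun with
# identical settings, and the observed number of significant regions compared
# to the permuted counts; (ii) classifier-based discrimination -- six
# standard classifiers evaluated by repeated stratified k-fold CV on the
# differential regions versus equally sized random region sets.

# one subject-level permutation of diagnosis; never the identity when
# alternatives exist
permute_diagnosis <- function(sheet) {
  subj <- unique(sheet$subject_id)
  diag_by_subj <- sheet$diagnosis[match(subj, sheet$subject_id)]
  if (length(unique(diag_by_subj)) < 2L)
    stop("need both diagnoses present to permute", call. = FALSE)
  repeat {
    perm <- sample(diag_by_subj)
    if (!identical(perm, diag_by_subj)) break
  }
  sheet$diagnosis <- perm[match(sheet$subject_id, subj)]
  sheet
}

#' Run the standard differential fit for one dataset
#'
#' Convenience wrapper bundling the standard settings: build the design,
#' estimate precision and sample weights, estimate the consensus block
#' correlation, and fit the moderated contrast. The permutation validation
#' reruns exactly this path per permuted dataset.
#'
#' @param norm region x sample normalized matrix.
#' @param sheet a [sample_sheet()] aligned to the matrix columns.
#' @param contrast contrast string (see [design_spec()]).
#' @param use_weights estimate precision/sample weights (default TRUE).
#' @return a `differential_table` (see [fit_differential()]).
#' @export
run_differential_once <- function(norm, sheet, contrast, use_weights = TRUE) {
  ds <- design_spec(sheet, contrast)
  ow <- if (use_weights) estimate_precision_weights(norm, ds$design) else NULL
  sw <- if (use_weights) estimate_sample_weights(norm, ds$design) else NULL
  rho <- estimate_block_correlation(norm, ds$design, ds$block)
  fit_differential(norm, ds, obs_weights = ow, sample_weights = sw,
                   block_correlation = rho)
}

#' Permutation validation of the differential set
#'
#' Permutes case/control status across subjects (both libraries of a subject
#' flip together, preserving the paired design), reruns the full differential
#' pipeline per permutation with identical settings, and reports the number
#' of regions significant at `fdr` for the observed and each permuted
#' dataset. The add-one empirical p is
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`, so a real signal whose
#' observed count exceeds all permutations scores `1/(n_perm+1)`. Also
#' reports the KS distance of the observed p-values from Uniform(0,1).
#'
#' @param norm region x sample normalized matrix.
#' @param sheet a [sample_sheet()] aligned to the matrix columns.
#' @param contrast contrast string (see [design_spec()]).
#' @param n_perm number of permuted datasets (default 100).
#' @param fdr q-value threshold counting a region as significant (default
#'   0.05).
#' @param use_weights recompute precision/sample weights per dataset
#'   (default TRUE).
#' @param seed integer seed.
#' @return list (classed `permutation_report`): `observed_n_significant`,
#'   `permuted_n_significant`, `empirical_p`, `uniformity`, `seed`.
#' @export
permutation_validation <- function(norm, sheet, contrast, n_perm = 100,
                                   fdr = 0.05, use_weights = TRUE, seed = 1L) {
  set.seed(check_count(seed, "seed", min = 0L))
  sheet <- sheet[match(colnames(norm), sheet$sample_id), , drop = FALSE]
  subj <- unique(sheet$subject_id)
  diag_by_subj <- sheet$diagnosis[match(subj, sheet$subject_id)]
  n_case <- sum(diag_by_subj == "case")
  space <- choose(length(subj), n_case)
  if (space - 1 < n_perm)
    warning("permutation space (", space, ") smaller than n_perm; ",
            "permutations drawn with replacement")
  obs_tab <- run_differential_once(norm, sheet, contrast, use_weights)
  observed <- sum(obs_tab$q_value < fdr)
  observed_minp <- min(obs_tab$p_value)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    ps <- permute_diagnosis(sheet)
    tab <- run_differential_once(norm, ps, contrast, use_weights)
    c(sum(tab$q_value < fdr), min(tab$p_value))
  }, numeric(2))
  permuted <- perm_stats[1, ]
  # "permuted >= observed" with ties between equal counts resolved by the
  # smallest per-region p-value (continuous), so the add-one empirical p is
  # uniform under the null instead of piling up on 1 when all counts are 0
  ge <- permuted > observed |
    (permuted == observed & perm_stats[2, ] <= observed_minp)
  structure(list(
    observed_n_significant = observed,
    permuted_n_significant = permuted,
    empirical_p = (1 + sum(ge)) / (n_perm + 1),
    uniformity = pvalue_uniformity(obs_tab$p_value),
    seed = seed
  ), class = "permutation_report")
}

#' P-value uniformity diagnostics
#'
#' One-sample Kolmogorov-Smirnov distance of the p-values from Uniform(0,1)
#' plus an expected-vs-observed quantile (QQ) table. Under a well-calibrated
#' null, p-values are uniform and the distance is small.
#'
#' @param pvalues numeric vector in `[0, 1]`, nonempty.
#' @return list with `ks_distance` and `qq` (data.frame `expected`,
#'   `observed`).
#' @export
pvalue_uniformity <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector", call. = FALSE)
  n <- length(pvalues)
  ks <- suppressWarnings(stats::ks.test(pvalues, "punif"))
  list(ks_distance = unname(ks$statistic),
       qq = data.frame(expected = (seq_len(n) - 0.5) / n,
                       observed = sort(pvalues)))
}

# --- classifier-based discrimination ------------------------------------

default_classifiers <- function() {
  list(
    naive_bayes = function(xtr, ytr, xte) {
      m <- e1071::naiveBayes(xtr, ytr)
      list(pred = stats::predict(m, xte),
           score = stats::predict(m, xte, type = "raw")[, levels(ytr)[2]])
    },
    random_forest = function(xtr, ytr, xte) {
      m <- randomForest::randomForest(xtr, ytr, ntree = 200)
      list(pred = stats::predict(m, xte),
           score = stats::predict(m, xte, type = "prob")[, levels(ytr)[2]])
    },
    knn = function(xtr, ytr, xte) {
      p <- class::knn(xtr, xte, ytr, k = 5, prob = TRUE)
      pr <- attr(p, "prob")
      list(pred = p,
           score = ifelse(p == levels(ytr)[2], pr, 1 - pr))
    },
    logistic = function(xtr, ytr, xte) {
      df <- data.frame(y = ytr, xtr)
      m <- nnet::multinom(y ~ ., df, trace = FALSE)
      sc <- stats::predict(m, data.frame(xte), type = "probs")
      list(pred = factor(ifelse(sc > 0.5, levels(ytr)[2], levels(ytr)[1]),
                         levels = levels(ytr)),
           score = sc)
    },
    svm_linear = function(xtr, ytr, xte) {
      m <- e1071::svm(xtr, ytr, kernel = "linear", probability = TRUE)
      p <- stats::predict(m, xte, probability = TRUE)
      list(pred = p,
           score = attr(p, "probabilities")[, levels(ytr)[2]])
    },
    svm_poly = function(xtr, ytr, xte) {
      m <- e1071::svm(xtr, ytr, kernel = "polynomial", probability = TRUE)
      p <- stats::predict(m, xte, probability = TRUE)
      list(pred = p,
           score = attr(p, "probabilities")[, levels(ytr)[2]])
    }
  )
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

cv_accuracy <- function(x, y, classifier, folds, repeats) {
  accs <- numeric(0); aucs <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    score <- numeric(length(y))
    for (k in seq_len(folds)) {
      te <- fold == k
      out <- classifier(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE])
      pred[te] <- out$pred
      score[te] <- out$score
    }
    accs <- c(accs, mean(pred == y))
    aucs <- c(aucs, as.numeric(suppressMessages(
      pROC::auc(pROC::roc(y, score, levels = levels(y), direction = "<",
                          quiet = TRUE)))))
  }
  c(acc_mean = mean(accs), acc_sd = stats::sd(accs), auc_mean = mean(aucs))
}

#' Classifier-based discrimination of the differential set
#'
#' Evaluates six classifiers (naive Bayes, random forest, nearest neighbor,
#' logistic regression, linear- and polynomial-kernel SVM) by repeated
#' stratified k-fold cross-validation on (a) the differential-region feature
#' matrix and (b) `n_random_draws` equally sized random region sets, and
#' reports the accuracy improvement `delta` per classifier.
#'
#' Note: the differential regions are supplied externally and were typically
#' selected on the full data, so the absolute accuracies are optimistic
#' (selection leakage); `delta` against size-matched random sets is the
#' meaningful readout. A leakage note is included in the report.
#'
#' @param norm region x sample matrix of features.
#' @param labels per-sample class labels (`case`/`control`).
#' @param differential_regions region ids forming the candidate feature set.
#' @param n_random_draws number of random region sets (default 10).
#' @param cv_folds folds (default 5).
#' @param cv_repeats repeats (default 10).
#' @param classifiers named list of classifier functions (default the six
#'   above).
#' @param seed integer seed.
#' @return data.frame (classed `ml_report`): per classifier the differential
#'   and random-set CV accuracy (mean, sd), AUC means, and `delta`; attribute
#'   `leakage_note` documents the selection caveat.
#' @export
ml_discrimination <- function(norm, labels, differential_regions,
                              n_random_draws = 10, cv_folds = 5,
                              cv_repeats = 10, classifiers = NULL, seed = 1L) {
  set.seed(check_count(seed, "seed", min = 0L))
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must have exactly 2 classes", call. = FALSE)
  if (min(table(y)) < cv_folds)
    stop("each class needs >= cv_folds samples", call. = FALSE)
  missing <- setdiff(differential_regions, rownames(norm))
  if (length(missing))
    stop("unknown region id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(classifiers)) classifiers <- default_classifiers()
  nd <- length(differential_regions)
  x_diff <- t(norm[differential_regions, , drop = FALSE])
  pool <- setdiff(rownames(norm), differential_regions)
  rows <- lapply(names(classifiers), function(nm) {
    cls <- classifiers[[nm]]
    d <- cv_accuracy(x_diff, y, cls, cv_folds, cv_repeats)
    rnd <- vapply(seq_len(n_random_draws), function(i) {
      xr <- t(norm[sample(pool, nd), , drop = FALSE])
      cv_accuracy(xr, y, cls, cv_folds, cv_repeats)
    }, numeric(3))
    data.frame(classifier = nm,
               diff_acc_mean = d[["acc_mean"]], diff_acc_sd = d[["acc_sd"]],
               diff_auc_mean = d[["auc_mean"]],
               random_acc_mean = mean(rnd["acc_mean", ]),
               random_acc_sd = stats::sd(rnd["acc_mean", ]),
               random_auc_mean = mean(rnd["auc_mean", ]),
               delta = d[["acc_mean"]] - mean(rnd["acc_mean", ]),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  attr(report, "leakage_note") <-
    paste("differential regions were selected on the full data;",
          "absolute accuracies are optimistic -- interpret delta vs",
          "size-matched random sets")
  class(report) <- c("ml_report", "data.frame")
  report
}
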