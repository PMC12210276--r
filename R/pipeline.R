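# Orchestration: reproducible end-to-end runs driven by a single config
# (YAML path or named list), writing CSV results plus a JSON provenance
# manifest (package version, seed, resolved parameters) per run.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  config
}

write_provenance <- function(out_dir, stage, params, seed) {
  manifest <- list(
    package = "ocrstats",
    version = as.character(utils::packageVersion("ocrstats")),
    stage = stage,
    seed = seed,
    parameters = params
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the ATAC differential pipeline end to end
#'
#' Stages, in order: load (or simulate) counts -> CPM filter -> TMM +
#' within-cell-type quantile normalization -> BIC covariate ledger ->
#' precision-weighted differential fit -> optional permutation validation.
#' Every stage writes a CSV and a JSON provenance block into `out_dir`; a
#' failure aborts with the stage name, preserving partial outputs.
#'
#' Config keys: either `counts`/`bed`/`sheet` file paths or `simulate` (a
#' list of [atac_sim_spec()] arguments); `contrast` (default the first cell
#' type); `candidates` (ledger covariates, default none); `normalization`
#' (list of [normalization_params()] arguments); `ledger` (list of
#' [ledger_config()] arguments); `validation` (list: `n_perm`, `fdr`, or
#' `NULL` to skip); `fdr` (significance threshold, default 0.05); `seed`.
#'
#' @param config list or YAML path.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main stage results.
#' @export
run_atac_pipeline <- function(config, out_dir) {
  config <- read_run_config(config)
  seed <- config$seed %||% 1L
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% seed
      sim <- simulate_atac_counts(do.call(atac_sim_spec, sim_args))
      counts <- sim$counts; sheet <- sim$sheet; truth <- sim$truth
    } else {
      loaded <- load_counts(config$counts, config$bed, config$sheet)
      counts <- loaded$counts; sheet <- loaded$sheet; truth <- NULL
    }

    stage <- "filter"
    np <- do.call(normalization_params, config$normalization %||% list())
    filt <- filter_low_signal(counts, np)
    utils::write.csv(data.frame(removed_region = filt$removed),
                     file.path(out_dir, "filter_removed.csv"),
                     row.names = FALSE)
    write_provenance(out_dir, "filter",
                     list(cpm_threshold = np$cpm_threshold,
                          min_fraction = np$min_fraction,
                          n_removed = length(filt$removed)), seed)

    stage <- "normalize"
    norm <- normalize_pipeline(filt$filtered, sheet, np)
    utils::write.csv(data.frame(sample = names(norm$tmm), tmm = norm$tmm),
                     file.path(out_dir, "tmm_factors.csv"), row.names = FALSE)
    write_provenance(out_dir, "normalize",
                     list(prior_count = np$prior_count,
                          quantile_group_key = np$quantile_group_key), seed)

    stage <- "ledger"
    candidates <- config$candidates %||% character(0)
    ledger <- NULL
    if (length(candidates)) {
      lc <- do.call(ledger_config,
                    c(list(candidates = candidates), config$ledger %||% list()))
      ledger <- bic_ledger(norm$norm, sheet, lc)
      utils::write.csv(as.data.frame(ledger),
                       file.path(out_dir, "bic_ledger.csv"), row.names = FALSE)
      write_provenance(out_dir, "ledger",
                       list(delta_bic = lc$delta_bic,
                            min_fraction = lc$min_fraction,
                            included = ledger$candidate[ledger$included]),
                       seed)
    }

    stage <- "differential"
    contrast <- config$contrast %||%
      paste0("case_vs_control@", sort(unique(sheet$cell_type))[1])
    tab <- run_differential_once(norm$norm, sheet, contrast)
    utils::write.csv(as.data.frame(tab),
                     file.path(out_dir, "differential_table.csv"),
                     row.names = FALSE)
    fdr <- config$fdr %||% 0.05
    write_provenance(out_dir, "differential",
                     list(contrast = contrast, fdr = fdr,
                          n_significant = sum(tab$q_value < fdr)), seed)

    stage <- "validation"
    perm <- NULL
    if (!is.null(config$validation)) {
      perm <- permutation_validation(norm$norm, sheet, contrast,
                                     n_perm = config$validation$n_perm %||% 100,
                                     fdr = config$validation$fdr %||% fdr,
                                     seed = seed)
      utils::write.csv(
        data.frame(permutation = seq_along(perm$permuted_n_significant),
                   n_significant = perm$permuted_n_significant),
        file.path(out_dir, "permutation_counts.csv"), row.names = FALSE)
      write_provenance(out_dir, "validation",
                       list(n_perm = length(perm$permuted_n_significant),
                            observed = perm$observed_n_significant,
                            empirical_p = perm$empirical_p), seed)
    }
    list(counts = counts, sheet = sheet, truth = truth, filtered = filt,
         norm = norm, ledger = ledger, differential = tab, permutation = perm)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Run the peri-event calcium pipeline end to end
#'
#' Stages: load (or simulate) session -> bout merging + modulation
#' classification -> state-restricted mean activity -> pairwise synchrony.
#' Outputs CSV reports plus JSON provenance into `out_dir`.
#'
#' Config keys: `traces`/`events` paths + `rate_hz`, or `simulate` (list of
#' [calcium_sim_spec()] arguments); `post_window_s`, `pre_window_s`,
#' `n_shuffles`, `alpha`, `min_gap_s`, `seed`.
#'
#' @param config list or YAML path.
#' @param out_dir output directory.
#' @return invisibly, list with `modulation`, `state_activity`, `synchrony`.
#' @export
run_perievent_pipeline <- function(config, out_dir) {
  config <- read_run_config(config)
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% seed
      sim <- simulate_calcium_session(do.call(calcium_sim_spec, sim_args))
      session <- sim$session
    } else {
      session <- load_calcium(config$traces, config$events, config$rate_hz)
    }

    stage <- "classify"
    mod <- classify_session(session,
                            post_window_s = config$post_window_s %||% c(1, 3),
                            pre_window_s = config$pre_window_s %||% c(-3, -1),
                            n_shuffles = config$n_shuffles %||% 1000,
                            alpha = config$alpha %||% 0.05,
                            min_gap_s = config$min_gap_s %||% 2.0,
                            seed = seed)
    utils::write.csv(as.data.frame(mod),
                     file.path(out_dir, "modulation_report.csv"),
                     row.names = FALSE)
    write_provenance(out_dir, "classify",
                     list(n_shuffles = attr(mod, "n_shuffles"),
                          alpha = attr(mod, "alpha")), seed)

    stage <- "state_activity"
    sa <- state_mean_activity(session)
    utils::write.csv(sa, file.path(out_dir, "state_activity.csv"),
                     row.names = FALSE)

    stage <- "synchrony"
    sy <- pairwise_synchrony(session)
    utils::write.csv(as.data.frame(sy),
                     file.path(out_dir, "synchrony_matrix.csv"),
                     row.names = TRUE)
    write_provenance(out_dir, "synchrony",
                     list(mean_offdiag = attr(sy, "mean_offdiag")), seed)
    list(session = session, modulation = mod, state_activity = sa,
         synchrony = sy)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
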