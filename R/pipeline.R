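#' Assemble a pipeline configuration
#'
#' Collects paths, thresholds and flags for [run_pipeline()]. A YAML file
#' with the same keys may be supplied instead; explicit arguments override
#' file values.
#'
#' @param config_file Optional YAML file of configuration keys.
#' @param ... Overrides: any of `out_dir`, `seed`, `peptide_file` (omit to
#'   simulate), `sim` (list of [pool_sim_config()] arguments), `gmt_file`,
#'   `ht_file`, `elisa_file`, `covariates`, `p_thresh`,
#'   `min_peptide_ratios`, `min_pairs`, `min_set_size`, `ridge_frac`,
#'   `max_perms`, `project_fold`, `require_concordance`,
#'   `unique_peptides`, `label_adjust_sets`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config_file = NULL, ...) {
  defaults <- list(
    out_dir = NULL, seed = 1L,
    peptide_file = NULL, sim = list(),
    gmt_file = NULL, ht_file = NULL, elisa_file = NULL,
    covariates = character(),
    p_thresh = 0.05, min_peptide_ratios = 4L, min_pairs = 2L,
    min_set_size = 3L, ridge_frac = 0.5, max_perms = 1e5,
    project_fold = NULL,
    require_concordance = FALSE, unique_peptides = FALSE,
    label_adjust_sets = TRUE
  )
  cfg <- defaults
  if (!is.null(config_file)) {
    from_file <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(from_file), names(defaults))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg[names(from_file)] <- from_file
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (is.null(cfg$out_dir)) stop("out_dir is required")
  if (cfg$p_thresh < 0 || cfg$p_thresh > 1) stop("p_thresh must be in [0, 1]")
  if (cfg$min_pairs < 2) stop("min_pairs must be >= 2")
  if (cfg$ridge_frac < 0) stop("ridge_frac must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Run the pooled-proteomics pipeline end to end
#'
#' Executes the configured stages in order: simulate (when no peptide
#' file is given) -> rollup and median centering -> per-disease exclusion
#' rules -> joint weighted model with empirical-Bayes moderated t and
#' per-disease FDR -> protein-set tests (when a GMT file is given) ->
#' candidate selection against a treatment-effect table (when given) ->
#' matched-pair replication statistics (when given). All stage outputs
#' are written as tab-separated tables under `out_dir`, along with a
#' machine-readable JSON run report carrying the seed, exclusion counts,
#' skipped sets and any warnings.
#'
#' @param config A `pipeline_config` (or arguments forwarded to
#'   [pipeline_config()]).
#' @return Invisibly, a list with the in-memory stage results and the
#'   `report`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("poolprot")),
                 seed = config$seed, warnings = character())

  # --- input stage -----------------------------------------------------
  if (!is.null(config$peptide_file)) {
    peptides <- read_peptide_table(config$peptide_file)
    truth <- NULL
  } else {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    sim <- generate_pool_experiments(do.call(pool_sim_config, sim_args))
    peptides <- sim$peptides
    truth <- sim$truth
    write_peptide_table(peptides, file.path(config$out_dir, "peptides.tsv"))
    write_tsv(data.frame(protein = names(truth$delta),
                         delta_log2 = truth$delta,
                         lambda_log2 = truth$lambda),
              file.path(config$out_dir, "truth.tsv"))
  }
  diseases <- unique(peptides$disease)

  # --- quant stage -----------------------------------------------------
  m <- center_by_experiment(rollup(peptides,
                                   unique_peptides = config$unique_peptides))
  retained <- list()
  report$exclusions <- list()
  for (d in diseases) {
    md <- apply_exclusions(m, peptides, d,
                           min_peptide_ratios = config$min_peptide_ratios,
                           min_pairs = config$min_pairs)
    retained[[d]] <- rownames(md$y)
    log <- attr(md, "exclusion_log")
    report$exclusions[[d]] <- stats::setNames(as.list(log$n), log$rule)
  }
  keep <- sort(unique(unlist(retained)))
  m_fit <- m
  m_fit$y <- m_fit$y[keep, , drop = FALSE]
  m_fit$w <- m_fit$w[keep, , drop = FALSE]
  write_protein_matrix(m_fit, file.path(config$out_dir, "protein_matrix.tsv"))

  # --- differential stage ----------------------------------------------
  fits <- fit_weighted_model(m_fit)
  hyper <- estimate_hyperparams(fits)
  res <- moderated_test(fits, hyper, min_pairs = config$min_pairs)
  res <- res[mapply(function(p, d) p %in% retained[[d]],
                    res$protein, res$disease), , drop = FALSE]
  res$fdr <- NA_real_
  for (d in unique(res$disease)) {
    i <- res$disease == d
    res$fdr[i] <- bh_adjust(res$p[i])
  }
  res <- res[order(res$disease, res$p), ]
  rownames(res) <- NULL
  write_diff_results(res, file.path(config$out_dir, "diff_results.tsv"))
  report$hyperparams <- list(d0 = hyper$d0, s02 = hyper$s02)
  report$n_tested <- as.list(table(res$disease))

  # --- set-test stage --------------------------------------------------
  set_res <- NULL
  if (!is.null(config$gmt_file)) {
    sets <- read_gmt(config$gmt_file)
    set_res <- list()
    report$skipped_sets <- list()
    for (d in diseases) {
      sr <- run_set_tests(m_fit, sets, d,
                          fits = if (config$label_adjust_sets) fits else NULL,
                          ridge_frac = config$ridge_frac,
                          max_perms = config$max_perms,
                          min_size = config$min_set_size,
                          seed = config$seed)
      set_res[[d]] <- sr
      write_set_results(sr, file.path(config$out_dir,
                                      paste0("set_results_", d, ".tsv")))
      sk <- attr(sr, "skipped")
      report$skipped_sets[[d]] <-
        if (is.null(sk)) list() else as.list(sk)
    }
  }

  # --- overlap stage ---------------------------------------------------
  candidates <- NULL
  if (!is.null(config$ht_file)) {
    ht <- read_ht_effects(config$ht_file)
    candidates <- list()
    for (d in unique(res$disease)) {
      cand <- select_candidates(res[res$disease == d, ], ht,
                                p_thresh = config$p_thresh,
                                require_concordance = config$require_concordance)
      candidates[[d]] <- cand
      write_tsv(cand, file.path(config$out_dir,
                                paste0("candidates_", d, ".tsv")))
    }
  }

  # --- replication stage -----------------------------------------------
  replication <- NULL
  if (!is.null(config$elisa_file)) {
    pairs <- read_elisa_pairs(config$elisa_file)
    gmr <- geometric_mean_ratio(pairs)
    adj <- adjusted_ratio_model(pairs, config$covariates)
    subjects <- pairs_to_subjects(pairs)
    ql <- quartile_logistic(subjects, config$covariates)
    slope <- log_concentration_slope(subjects, config$covariates)
    proj <- if (!is.null(config$project_fold))
      project_or(slope$beta, slope$se, config$project_fold) else NULL
    summary_tab <- data.frame(
      quantity = c("gmr", "gmr_lo", "gmr_hi", "gmr_p",
                   "adj_gmr", "adj_gmr_lo", "adj_gmr_hi",
                   "or_q2", "or_q3", "or_q4", "trend_p",
                   "log_slope", "log_slope_se",
                   if (!is.null(proj)) c("projected_or", "projected_or_lo",
                                         "projected_or_hi")),
      value = c(gmr$gmr, gmr$ci, gmr$p,
                adj$gmr, adj$ci,
                ql$or, ql$trend_p,
                slope$beta, slope$se,
                if (!is.null(proj)) c(proj$or, proj$ci))
    )
    write_tsv(summary_tab, file.path(config$out_dir,
                                     "replication_summary.tsv"))
    replication <- list(gmr = gmr, adjusted = adj, quartiles = ql,
                        slope = slope, projection = proj)
  }

  jsonlite::write_json(report,
                       file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(peptides = peptides, truth = truth, matrix = m_fit,
                 fits = fits, hyper = hyper, results = res,
                 set_results = set_res, candidates = candidates,
                 replication = replication, report = report))
}
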