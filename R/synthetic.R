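#' Configuration for a pooled case-control proteomics simulation
#'
#' Describes a set of pooled isotope-labeling experiments: for each disease a
#' number of case/control pool pairs, per-protein true log2 case-vs-control
#' effects, a shared labeling bias that enters with sign +/-1 according to
#' which pool received the heavy label, protein-by-experiment noise,
#' peptide-level noise, a peptides-per-protein law and a missingness rate.
#'
#' Defaults emulate the discovery design this package targets: 8 pool pairs
#' per disease, the heavy label always on the case pool for CHD and randomly
#' assigned for stroke, a few hundred quantifiable proteins of which a
#' modest fraction carry true effects of a magnitude typical of plasma
#' case-control log2 ratios.
#'
#' @param diseases Character vector of disease labels.
#' @param pairs_per_disease Number of case/control pool pairs per disease
#'   (>= 2).
#' @param n_proteins Number of protein groups.
#' @param frac_differential Fraction of proteins carrying a true effect,
#'   used when `effect_log2` is a single magnitude.
#' @param effect_log2 Either a single magnitude assigned (with random sign)
#'   to `frac_differential` of the proteins, or a full-length numeric vector
#'   of per-protein true log2 case/control effects.
#' @param label_bias_log2 Shared labeling bias (log2): the heavy channel is
#'   inflated by this amount regardless of which pool it labels.
#' @param label_scheme Per-disease label-assignment rule, `"random"` or
#'   `"always_case"`. Either a single value recycled to all diseases or a
#'   named vector/list keyed by disease.
#' @param sigma_protein SD (log2) of protein-by-experiment noise.
#' @param sigma_peptide SD (log2) of within-protein peptide noise.
#' @param peptide_count_law Function `n -> integer vector` drawing the
#'   number of quantified peptides for n protein-by-experiment cells;
#'   a draw of 0 yields a missing cell. Default: 1 + Poisson(3).
#' @param missing_rate Probability that a protein-by-experiment cell is
#'   missing outright (applied before the count law).
#' @param depleted_proteins,defunct_proteins Optional protein ids flagged
#'   as depletion targets / defunct in the emitted table.
#' @param seed Integer seed controlling all randomness of the generator.
#' @return An object of class `pool_sim_config`.
#' @export
pool_sim_config <- function(diseases = c("CHD", "stroke"),
                            pairs_per_disease = 8L,
                            n_proteins = 400L,
                            frac_differential = 0.1,
                            effect_log2 = 0.4,
                            label_bias_log2 = 0.15,
                            label_scheme = c(CHD = "always_case",
                                             stroke = "random"),
                            sigma_protein = 0.2,
                            sigma_peptide = 0.3,
                            peptide_count_law = function(n) 1L + stats::rpois(n, 3),
                            missing_rate = 0.25,
                            depleted_proteins = character(),
                            defunct_proteins = character(),
                            seed = 1L) {
  stopifnot(length(diseases) >= 1, !anyDuplicated(diseases))
  if (pairs_per_disease < 2)
    stop("pairs_per_disease must be >= 2")
  if (sigma_protein < 0 || sigma_peptide < 0)
    stop("noise SDs must be >= 0")
  if (frac_differential < 0 || frac_differential > 1)
    stop("frac_differential must be in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  if (!is.function(peptide_count_law))
    stop("peptide_count_law must be a function")
  scheme <- label_scheme
  if (is.null(names(scheme))) {
    if (length(scheme) == 1) scheme <- stats::setNames(rep(scheme, length(diseases)), diseases)
    else if (length(scheme) == length(diseases)) names(scheme) <- diseases
    else stop("label_scheme must be length 1 or match diseases")
  }
  scheme <- unlist(scheme)[diseases]
  if (any(is.na(scheme)) || !all(scheme %in% c("random", "always_case")))
    stop("label_scheme entries must be 'random' or 'always_case', one per disease")
  if (is.numeric(effect_log2) && length(effect_log2) != 1 &&
      length(effect_log2) != n_proteins)
    stop("effect_log2 must be a scalar magnitude or length n_proteins")
  structure(list(
    diseases = as.character(diseases),
    pairs_per_disease = as.integer(pairs_per_disease),
    n_proteins = as.integer(n_proteins),
    frac_differential = frac_differential,
    effect_log2 = effect_log2,
    label_bias_log2 = label_bias_log2,
    label_scheme = scheme,
    sigma_protein = sigma_protein,
    sigma_peptide = sigma_peptide,
    peptide_count_law = peptide_count_law,
    missing_rate = missing_rate,
    depleted_proteins = depleted_proteins,
    defunct_proteins = defunct_proteins,
    seed = as.integer(seed)
  ), class = "pool_sim_config")
}

#' Generate pooled heavy/light peptide ratio tables with known truth
#'
#' Simulates one pooled isotope-labeling experiment per pool pair. For
#' protein g in experiment i of disease d, each quantified peptide's true
#' log2 case/control ratio is
#' `delta_g + lambda * x_i + e_gi + eps`, where `x_i` is +1 when the heavy
#' label is on the case pool and -1 otherwise, `e_gi` is protein-by-
#' experiment noise and `eps` peptide noise. Areas are emitted with
#' `light_area = 1` and `heavy_area = 2^(x_i * ratio)`, so the heavy/light
#' orientation depends on the label assignment and downstream rollup must
#' unmix it via `x_i`.
#'
#' @param config A [pool_sim_config()] object.
#' @return A list of class `pool_experiments` with components
#'   `peptides` (the peptide ratio table, one row per quantified peptide
#'   per protein per pool pair) and `truth` (list with per-protein `delta`,
#'   scalar `lambda`, and the per-pair table of `experiment_id`, `disease`,
#'   `pair_index`, `x`).
#' @export
generate_pool_experiments <- function(config) {
  if (!inherits(config, "pool_sim_config"))
    stop("config must be a pool_sim_config")
  set.seed(config$seed)

  n <- config$n_proteins
  proteins <- sprintf("P%04d", seq_len(n))
  if (length(config$effect_log2) == n) {
    delta <- as.numeric(config$effect_log2)
  } else {
    delta <- numeric(n)
    n_diff <- round(config$frac_differential * n)
    if (n_diff > 0) {
      idx <- sample.int(n, n_diff)
      delta[idx] <- config$effect_log2 * sample(c(-1, 1), n_diff, replace = TRUE)
    }
  }
  names(delta) <- proteins
  lambda <- config$label_bias_log2

  pairs <- do.call(rbind, lapply(config$diseases, function(d) {
    idx <- seq_len(config$pairs_per_disease)
    x <- if (config$label_scheme[[d]] == "always_case") rep(1L, length(idx))
         else sample(c(-1L, 1L), length(idx), replace = TRUE)
    data.frame(experiment_id = sprintf("%s_%02d", d, idx),
               disease = d, pair_index = idx, x = x,
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL

  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    present <- stats::runif(n) >= config$missing_rate
    k <- integer(n)
    k[present] <- config$peptide_count_law(sum(present))
    present <- k > 0
    if (!any(present)) next
    e_gi <- stats::rnorm(n, 0, config$sigma_protein)
    kk <- k[present]
    prot <- rep(proteins[present], kk)
    base <- rep(delta[present] + lambda * pairs$x[i] + e_gi[present], kk)
    ratio <- base + stats::rnorm(length(prot), 0, config$sigma_peptide)
    pep <- sequence(kk)
    rows[[i]] <- data.frame(
      experiment_id = pairs$experiment_id[i],
      disease = pairs$disease[i],
      pair_index = pairs$pair_index[i],
      label_on_case = pairs$x[i] > 0,
      protein_group_id = prot,
      peptide_id = paste0(prot, "_pep", pep),
      heavy_area = 2 ^ (pairs$x[i] * ratio),
      light_area = 1,
      is_depleted_target = prot %in% config$depleted_proteins,
      is_defunct = prot %in% config$defunct_proteins,
      stringsAsFactors = FALSE
    )
  }
  peptides <- do.call(rbind, rows)
  rownames(peptides) <- NULL
  structure(list(peptides = peptides,
                 truth = list(delta = delta, lambda = lambda, pairs = pairs)),
            class = "pool_experiments")
}

#' Configuration for matched-pair immunoassay simulation
#'
#' Emulates a replication arm in which individual case and matched control
#' plasma samples are assayed for one protein: concentrations are
#' log-normal with the case member shifted by `log(true_gmr)`. Covariates
#' are drawn per pair and, by default, applied symmetrically to both
#' members (so they cancel in the within-pair ratio); a covariate
#' configured `asymmetric = TRUE` acts on the case member only and can
#' therefore confound the ratio.
#'
#' @param n_pairs Number of matched pairs (>= 3).
#' @param true_gmr True multiplicative case/control geometric mean ratio.
#' @param sigma_log SD of individual natural-log concentrations.
#' @param covariate_effects Named list; each element a list with fields
#'   `beta` (slope on log concentration), and optionally `mean` (default 0),
#'   `sd` (default 1) for the per-pair covariate draw, and `asymmetric`
#'   (default FALSE).
#' @param seed Integer seed.
#' @return An object of class `elisa_sim_config`.
#' @export
elisa_sim_config <- function(n_pairs = 106L, true_gmr = 1.18,
                             sigma_log = 0.3, covariate_effects = list(),
                             seed = 1L) {
  if (n_pairs < 3) stop("n_pairs must be >= 3")
  if (true_gmr <= 0) stop("true_gmr must be > 0")
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  if (length(covariate_effects) && is.null(names(covariate_effects)))
    stop("covariate_effects must be a named list")
  structure(list(n_pairs = as.integer(n_pairs), true_gmr = true_gmr,
                 sigma_log = sigma_log,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "elisa_sim_config")
}

#' Generate matched-pair immunoassay concentrations
#'
#' @param config An [elisa_sim_config()] object.
#' @return A data.frame (ElisaPairTable) with columns `pair_id`,
#'   `case_conc`, `control_conc` and one column per configured covariate
#'   (the per-pair covariate value).
#' @export
generate_elisa_pairs <- function(config) {
  if (!inherits(config, "elisa_sim_config"))
    stop("config must be an elisa_sim_config")
  set.seed(config$seed)
  n <- config$n_pairs
  base <- stats::rnorm(n, 0, 1)            # pair-level baseline abundance
  log_case <- base + log(config$true_gmr) + stats::rnorm(n, 0, config$sigma_log)
  log_ctrl <- base + stats::rnorm(n, 0, config$sigma_log)
  covs <- list()
  for (nm in names(config$covariate_effects)) {
    eff <- config$covariate_effects[[nm]]
    mu <- if (is.null(eff$mean)) 0 else eff$mean
    sdv <- if (is.null(eff$sd)) 1 else eff$sd
    z <- stats::rnorm(n, mu, sdv)
    log_case <- log_case + eff$beta * z
    if (!isTRUE(eff$asymmetric)) log_ctrl <- log_ctrl + eff$beta * z
    covs[[nm]] <- z
  }
  out <- data.frame(pair_id = sprintf("pair%04d", seq_len(n)),
                    case_conc = exp(log_case),
                    control_conc = exp(log_ctrl),
                    stringsAsFactors = FALSE)
  for (nm in names(covs)) out[[nm]] <- covs[[nm]]
  out
}
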