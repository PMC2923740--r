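#' Validate a peptide ratio table
#'
#' Checks the column contract of a peptide-level heavy/light quantification
#' table: one row per quantified peptide per protein group per pool pair,
#' with strictly positive areas and a label assignment that is constant
#' within each experiment.
#'
#' @param peptides A data.frame with columns `experiment_id`, `disease`,
#'   `pair_index`, `label_on_case`, `protein_group_id`, `peptide_id`,
#'   `heavy_area`, `light_area`, `is_depleted_target`, `is_defunct`.
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending column or row.
#' @export
validate_peptide_table <- function(peptides) {
  required <- c("experiment_id", "disease", "pair_index", "label_on_case",
                "protein_group_id", "peptide_id", "heavy_area", "light_area",
                "is_depleted_target", "is_defunct")
  missing_cols <- setdiff(required, names(peptides))
  if (length(missing_cols))
    stop("peptide table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(peptides) == 0) stop("peptide table is empty")
  bad <- which(!(peptides$heavy_area > 0 & peptides$light_area > 0))
  if (length(bad))
    stop("non-positive peak area at row ", bad[1],
         " (protein ", peptides$protein_group_id[bad[1]], ")")
  lab <- tapply(peptides$label_on_case, peptides$experiment_id,
                function(v) length(unique(v)))
  if (any(lab > 1))
    stop("label_on_case varies within experiment ",
         names(lab)[which(lab > 1)[1]])
  invisible(peptides)
}

#' Roll peptide heavy/light ratios up to protein-group log2 case/control ratios
#'
#' Each peptide's measured `log2(heavy/light)` is converted to the
#' case/control orientation by multiplying with `x_i` (+1 if the heavy
#' label was on the case pool of that experiment, -1 otherwise), then
#' summarized per protein group per pool pair. The per-cell summary is the
#' median of the peptide log2 ratios (a robust choice; the mean is
#' available), and the cell weight is the number of contributing peptide
#' ratio records (optionally the number of distinct peptide sequences).
#'
#' @param peptides A peptide ratio table (see [validate_peptide_table()]).
#' @param summary `"median"` (default) or `"mean"` per-cell summary.
#' @param unique_peptides If `TRUE`, weights count distinct `peptide_id`s
#'   rather than peptide ratio records.
#' @return An object of class `protein_ratio_matrix`: a list with
#'   `y` (proteins x pool-pairs matrix of log2 case/control ratios, `NA`
#'   for missing cells), `w` (matching matrix of peptide-count weights),
#'   `pairs` (per-column metadata: `experiment_id`, `disease`,
#'   `pair_index`, `x`), and `centering` (per-experiment constants, `NA`
#'   until [center_by_experiment()] is applied).
#' @export
rollup <- function(peptides, summary = c("median", "mean"),
                   unique_peptides = FALSE) {
  summary <- match.arg(summary)
  validate_peptide_table(peptides)
  x <- ifelse(peptides$label_on_case, 1, -1)
  ratio <- x * log2(peptides$heavy_area / peptides$light_area)

  exp_ids <- unique(peptides$experiment_id)
  prot_ids <- sort(unique(peptides$protein_group_id))
  cell <- interaction(factor(peptides$protein_group_id, levels = prot_ids),
                      factor(peptides$experiment_id, levels = exp_ids),
                      drop = TRUE, sep = "\r")
  fun <- if (summary == "median") stats::median else mean
  vals <- tapply(ratio, cell, fun)
  wts <- if (unique_peptides) {
    tapply(peptides$peptide_id, cell, function(p) length(unique(p)))
  } else {
    tapply(ratio, cell, length)
  }
  key <- strsplit(names(vals), "\r", fixed = TRUE)
  y <- matrix(NA_real_, length(prot_ids), length(exp_ids),
              dimnames = list(prot_ids, exp_ids))
  w <- matrix(NA_real_, length(prot_ids), length(exp_ids),
              dimnames = list(prot_ids, exp_ids))
  pi <- match(vapply(key, `[`, "", 1L), prot_ids)
  ei <- match(vapply(key, `[`, "", 2L), exp_ids)
  y[cbind(pi, ei)] <- as.numeric(vals)
  w[cbind(pi, ei)] <- as.numeric(wts)

  first <- !duplicated(peptides$experiment_id)
  pairs <- data.frame(
    experiment_id = peptides$experiment_id[first],
    disease = peptides$disease[first],
    pair_index = peptides$pair_index[first],
    x = ifelse(peptides$label_on_case[first], 1L, -1L),
    stringsAsFactors = FALSE
  )
  pairs <- pairs[match(exp_ids, pairs$experiment_id), ]
  rownames(pairs) <- NULL
  structure(list(y = y, w = w, pairs = pairs,
                 centering = stats::setNames(rep(NA_real_, length(exp_ids)),
                                             exp_ids)),
            class = "protein_ratio_matrix")
}

#' @export
print.protein_ratio_matrix <- function(x, ...) {
  cat("protein_ratio_matrix:", nrow(x$y), "protein groups x",
      ncol(x$y), "pool pairs\n")
  cat("  diseases:", paste(unique(x$pairs$disease), collapse = ", "), "\n")
  cat("  quantified cells:", sum(!is.na(x$y)), "of", length(x$y), "\n")
  cat("  centered:", !anyNA(x$centering), "\n")
  invisible(x)
}

#' Median-center protein log2 ratios within each experiment
#'
#' Subtracts, per experiment (pool pair), the median of the protein-level
#' log2 ratios present in that experiment, so that the within-experiment
#' median is exactly zero. The subtracted constants are stored in
#' `$centering`.
#'
#' @param m A `protein_ratio_matrix`.
#' @return The centered `protein_ratio_matrix`.
#' @export
center_by_experiment <- function(m) {
  stopifnot(inherits(m, "protein_ratio_matrix"))
  n_present <- colSums(!is.na(m$y))
  if (any(n_present == 0))
    stop("experiment with zero quantified proteins: ",
         colnames(m$y)[which(n_present == 0)[1]])
  ce <- apply(m$y, 2, stats::median, na.rm = TRUE)
  m$y <- sweep(m$y, 2, ce)
  m$centering <- stats::setNames(ce, colnames(m$y))
  m
}

#' Apply protein-group exclusion rules for one disease
#'
#' Retains protein groups that (in a documented order, counts attributed
#' to the first triggering rule): are not depletion targets; are not
#' all-defunct; have at least `min_peptide_ratios` peptide ratio records
#' summed across the disease's experiments; and are quantified in at
#' least `min_pairs` pool pairs of the disease.
#'
#' @param m A `protein_ratio_matrix` (all diseases' columns retained so a
#'   joint model can still be fit on the surviving protein groups).
#' @param peptides The peptide ratio table the matrix was rolled up from.
#' @param disease Disease label whose rules are applied.
#' @param min_peptide_ratios Minimum peptide ratio records across the
#'   disease's experiments (default 4).
#' @param min_pairs Minimum pool pairs with a quantified ratio (default 2).
#' @return The filtered `protein_ratio_matrix` (rows subset, all columns
#'   kept) with attribute `exclusion_log`, a data.frame of per-rule
#'   exclusion counts plus the retained count, and attribute `disease`.
#' @export
apply_exclusions <- function(m, peptides, disease,
                             min_peptide_ratios = 4L, min_pairs = 2L) {
  stopifnot(inherits(m, "protein_ratio_matrix"))
  if (!disease %in% m$pairs$disease)
    stop("unknown disease label: ", disease)
  prot <- rownames(m$y)
  pep_d <- peptides[peptides$disease == disease, , drop = FALSE]

  depleted <- tapply(pep_d$is_depleted_target, pep_d$protein_group_id, any)
  defunct <- tapply(pep_d$is_defunct, pep_d$protein_group_id, all)
  n_ratios <- table(factor(pep_d$protein_group_id, levels = prot))
  d_cols <- m$pairs$disease == disease
  n_pairs_quant <- rowSums(!is.na(m$y[, d_cols, drop = FALSE]))

  is_depleted <- prot %in% names(depleted)[depleted %in% TRUE]
  is_defunct <- prot %in% names(defunct)[defunct %in% TRUE]
  few_ratios <- as.integer(n_ratios[prot]) < min_peptide_ratios
  few_pairs <- n_pairs_quant < min_pairs

  reason <- rep(NA_character_, length(prot))
  reason[few_pairs] <- "fewer_than_min_pool_pairs"
  reason[few_ratios] <- "fewer_than_min_peptide_ratios"
  reason[is_defunct] <- "all_defunct"
  reason[is_depleted] <- "depletion_target"

  keep <- is.na(reason)
  log <- data.frame(
    rule = c("depletion_target", "all_defunct",
             "fewer_than_min_peptide_ratios", "fewer_than_min_pool_pairs",
             "retained"),
    n = c(sum(reason == "depletion_target", na.rm = TRUE),
          sum(reason == "all_defunct", na.rm = TRUE),
          sum(reason == "fewer_than_min_peptide_ratios", na.rm = TRUE),
          sum(reason == "fewer_than_min_pool_pairs", na.rm = TRUE),
          sum(keep)),
    stringsAsFactors = FALSE
  )
  m$y <- m$y[keep, , drop = FALSE]
  m$w <- m$w[keep, , drop = FALSE]
  attr(m, "exclusion_log") <- log
  attr(m, "disease") <- disease
  m
}
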