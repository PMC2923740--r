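#' Convert a log2 ratio to a multiplicative fold-change
#'
#' @param x Finite numeric log2 ratio(s).
#' @return `2^x`; no rounding is applied.
#' @export
log2_to_fold <- function(x) {
  if (any(!is.finite(x))) stop("log2 ratios must be finite")
  2^x
}

#' Expected number of nominally significant tests under the null
#'
#' @param n_tests Number of tests performed (>= 0).
#' @param alpha Nominal significance level in \[0, 1\].
#' @return `n_tests * alpha`.
#' @export
expected_by_chance <- function(n_tests, alpha = 0.05) {
  if (n_tests < 0) stop("n_tests must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  n_tests * alpha
}

#' Select candidate mediators concordant between disease and treatment
#'
#' Inner-joins per-protein disease differential results with a
#' treatment-effect table carrying, per protein, the log2 1-year change
#' and p-value under each of two hormone-therapy arms (E+P and E-alone).
#' A protein is selected when its disease p-value and at least one arm's
#' p-value fall below `p_thresh`. Concordance is judged on the sign of
#' the log2 effects only: an arm is concordant when it is significant and
#' its direction matches the disease direction. With
#' `require_concordance = TRUE`, every significant arm must be
#' concordant.
#'
#' @param diff Data.frame with columns `protein`, `log2_ratio`, `p` and
#'   optionally `fdr` (one disease's differential results).
#' @param ht Data.frame with columns `protein`, `ep_log2`, `ep_p`,
#'   `ealone_log2`, `ealone_p`.
#' @param p_thresh Significance threshold applied to both sides
#'   (default 0.05).
#' @param require_concordance Drop rows with a significant discordant arm
#'   (default FALSE).
#' @return A data.frame (CandidateTable) with the joined effects,
#'   per-arm concordance flags, an overall `concordant` flag and a
#'   `rationale` string; zero rows when nothing qualifies.
#' @export
select_candidates <- function(diff, ht, p_thresh = 0.05,
                              require_concordance = FALSE) {
  stopifnot(all(c("protein", "log2_ratio", "p") %in% names(diff)),
            all(c("protein", "ep_log2", "ep_p", "ealone_log2", "ealone_p")
                %in% names(ht)))
  if (anyDuplicated(diff$protein))
    stop("duplicate protein ids in differential table")
  if (anyDuplicated(ht$protein))
    stop("duplicate protein ids in treatment-effect table")
  joined <- merge(diff, ht, by = "protein")
  if (nrow(joined) == 0) return(joined[, , drop = FALSE])

  dis_sig <- joined$p < p_thresh
  ep_sig <- !is.na(joined$ep_p) & joined$ep_p < p_thresh
  ea_sig <- !is.na(joined$ealone_p) & joined$ealone_p < p_thresh
  keep <- dis_sig & (ep_sig | ea_sig)

  conc_ep <- ep_sig & sign(joined$ep_log2) == sign(joined$log2_ratio)
  conc_ea <- ea_sig & sign(joined$ealone_log2) == sign(joined$log2_ratio)
  all_conc <- (!ep_sig | conc_ep) & (!ea_sig | conc_ea)
  if (require_concordance) keep <- keep & all_conc

  out <- joined[keep, , drop = FALSE]
  out$concordant_ep <- conc_ep[keep]
  out$concordant_ealone <- conc_ea[keep]
  out$concordant <- all_conc[keep]
  out$rationale <- sprintf(
    "disease p=%.3g; arms significant: %s%s",
    out$p,
    ifelse(ep_sig[keep], "E+P ", ""),
    ifelse(ea_sig[keep], "E-alone", "")
  )
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
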