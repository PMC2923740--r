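#' Extract a dense, label-adjusted sub-matrix for one protein set
#'
#' Restricts the protein ratio matrix to one disease's pool pairs and the
#' set's member proteins quantified there. Values are label-adjusted,
#' `y_gi - lambda_g * x_i`, using per-protein labeling coefficients from a
#' `model_fits` object (aliased or absent coefficients are treated as 0),
#' so a labeling bias cannot masquerade as a set effect. Missing cells are
#' imputed with the protein's mean over its observed pairs; the number of
#' imputed cells is recorded.
#'
#' @param m A `protein_ratio_matrix`.
#' @param set Character vector of member protein ids.
#' @param disease Disease label.
#' @param fits Optional `model_fits` for label adjustment (`NULL` skips
#'   adjustment).
#' @param min_size Minimum quantified member proteins (default 3); below
#'   this the set is skipped and `NULL` returned.
#' @return A dense members x pool-pairs matrix with attributes
#'   `n_imputed` and `x` (per-column label assignment), or `NULL` if the
#'   set has too few quantified members.
#' @export
prepare_set_matrix <- function(m, set, disease, fits = NULL, min_size = 3L) {
  stopifnot(inherits(m, "protein_ratio_matrix"))
  if (!disease %in% m$pairs$disease)
    stop("unknown disease label: ", disease)
  cols <- which(m$pairs$disease == disease)
  members <- intersect(set, rownames(m$y))
  if (length(members)) {
    quantified <- rowSums(!is.na(m$y[members, cols, drop = FALSE])) > 0
    members <- members[quantified]
  }
  if (length(members) < min_size) return(NULL)
  sub <- m$y[members, cols, drop = FALSE]
  x <- m$pairs$x[cols]
  if (!is.null(fits)) {
    lam <- fits$lambda[members]
    lam[is.na(lam)] <- 0
    sub <- sub - outer(lam, x)
  }
  n_imputed <- sum(is.na(sub))
  if (n_imputed > 0) {
    rm_ <- rowMeans(sub, na.rm = TRUE)
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- rm_[idx[, 1]]
  }
  attr(sub, "n_imputed") <- n_imputed
  attr(sub, "x") <- x
  sub
}

#' Regularized Hotelling T-squared statistic
#'
#' For an m x n matrix of per-protein log2 ratios over n pool pairs, with
#' row means `ybar` and sample covariance `S` across pairs, the ridge is
#' `r = ridge_frac * mean(diag(S))` and the statistic
#' `T2 = n * ybar' (S + r I)^{-1} ybar`. The ridge keeps the covariance
#' invertible when the set size approaches or exceeds the number of pool
#' pairs, and scales with the data so the statistic is equivariant under
#' common rescaling.
#'
#' @param sub Numeric matrix, proteins in rows, pool pairs in columns
#'   (n >= 2 columns).
#' @param ridge_frac Positive scalar fraction of the mean diagonal of `S`
#'   used as ridge (default 0.5).
#' @return A list with `T2` and the ridge `r` used.
#' @export
hotelling_t2_reg <- function(sub, ridge_frac = 0.5) {
  if (!is.matrix(sub)) sub <- matrix(sub, nrow = 1)
  n <- ncol(sub)
  if (n < 2) stop("need at least 2 pool pairs (columns)")
  if (any(!is.finite(sub))) stop("non-finite entries in set matrix")
  if (ridge_frac < 0) stop("ridge_frac must be >= 0")
  ybar <- rowMeans(sub)
  S <- stats::cov(t(sub))
  r <- ridge_frac * mean(diag(S))
  if (all(ybar == 0)) return(list(T2 = 0, r = r))
  A <- S + diag(r, nrow(sub))
  T2 <- n * drop(crossprod(ybar, solve(A, ybar)))
  list(T2 = T2, r = r)
}

#' Sign-flip permutation p-value for the regularized T-squared
#'
#' The null hypothesis of no case/control difference makes each pool
#' pair's log2 ratio vector symmetric about zero, so flipping the signs of
#' whole columns generates the null distribution. With `2^n <= max_perms`
#' all sign assignments are enumerated exactly and the p-value counts the
#' observed (identity) assignment in both numerator and denominator, so
#' the minimum attainable p is `1 / 2^n`. Otherwise `max_perms` random
#' assignments are drawn and the add-one estimator
#' `(1 + #exceedances) / (1 + max_perms)` is used.
#'
#' @param sub Numeric matrix, proteins x pool pairs (n >= 3 columns).
#' @param ridge_frac Ridge fraction passed to [hotelling_t2_reg()].
#' @param max_perms Permutation budget (default 1e5).
#' @param seed Optional seed for the Monte-Carlo branch.
#' @return The permutation p-value, with attributes `T2` (observed
#'   statistic), `n_perms` and `exact`.
#' @export
signflip_pvalue <- function(sub, ridge_frac = 0.5, max_perms = 1e5,
                            seed = NULL) {
  if (!is.matrix(sub)) sub <- matrix(sub, nrow = 1)
  n <- ncol(sub)
  if (n < 3) stop("need at least 3 pool pairs for a sign-flip null")
  obs <- hotelling_t2_reg(sub, ridge_frac)$T2
  exact <- 2^n <= max_perms
  if (exact) {
    nperm <- 2^n
    count <- 0L
    for (k in 0:(nperm - 1)) {
      signs <- 1 - 2 * as.integer(intToBits(k)[seq_len(n)])
      t2 <- hotelling_t2_reg(sweep(sub, 2, signs, `*`), ridge_frac)$T2
      if (t2 >= obs - 1e-12) count <- count + 1L
    }
    p <- count / nperm
  } else {
    if (!is.null(seed)) set.seed(seed)
    nperm <- max_perms
    count <- 0L
    for (k in seq_len(nperm)) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      t2 <- hotelling_t2_reg(sweep(sub, 2, signs, `*`), ridge_frac)$T2
      if (t2 >= obs - 1e-12) count <- count + 1L
    }
    p <- (1 + count) / (1 + nperm)
  }
  attr(p, "T2") <- obs
  attr(p, "n_perms") <- nperm
  attr(p, "exact") <- exact
  p
}

#' Run regularized T-squared tests over a collection of protein sets
#'
#' Applies [prepare_set_matrix()], [hotelling_t2_reg()] and
#' [signflip_pvalue()] to each set for one disease, then adjusts the
#' permutation p-values by Benjamini-Hochberg across the tested sets.
#'
#' @param m A `protein_ratio_matrix`.
#' @param sets Named list of character vectors of member protein ids.
#' @param disease Disease label.
#' @param fits Optional `model_fits` for label adjustment.
#' @param ridge_frac Ridge fraction (default 0.5).
#' @param max_perms Permutation budget per set (default 1e5).
#' @param min_size Minimum quantified members (default 3).
#' @param seed Optional seed for Monte-Carlo permutation branches.
#' @return A data.frame with one row per tested set: `set`, `m`, `n`,
#'   `T2`, `ridge`, `p`, `fdr`, `n_imputed`, `members`
#'   (comma-separated), plus attribute `skipped` listing sets excluded
#'   with reasons.
#' @export
run_set_tests <- function(m, sets, disease, fits = NULL, ridge_frac = 0.5,
                          max_perms = 1e5, min_size = 3L, seed = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  rows <- list()
  skipped <- list()
  for (nm in names(sets)) {
    sub <- prepare_set_matrix(m, sets[[nm]], disease, fits = fits,
                              min_size = min_size)
    if (is.null(sub)) {
      skipped[[nm]] <- sprintf("m < %d", min_size)
      next
    }
    ht <- hotelling_t2_reg(sub, ridge_frac)
    p <- signflip_pvalue(sub, ridge_frac, max_perms, seed = seed)
    rows[[nm]] <- data.frame(
      set = nm, m = nrow(sub), n = ncol(sub),
      T2 = ht$T2, ridge = ht$r, p = as.numeric(p),
      n_imputed = attr(sub, "n_imputed"),
      members = paste(rownames(sub), collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows))
    stop("no set has >= ", min_size, " quantified members for ", disease)
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p, n_total = nrow(out))
  out <- out[order(out$p), c("set", "m", "n", "T2", "ridge", "p", "fdr",
                             "n_imputed", "members")]
  rownames(out) <- NULL
  attr(out, "skipped") <- unlist(skipped)
  out
}
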