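# Builders for small in-code fixtures shared across test files.

# One peptide table row; areas default to a unit ratio.
pep_row <- function(experiment_id = "CHD_01", disease = "CHD",
                    pair_index = 1L, label_on_case = TRUE,
                    protein_group_id = "P1", peptide_id = "P1_pep1",
                    heavy_area = 1, light_area = 1,
                    is_depleted_target = FALSE, is_defunct = FALSE) {
  data.frame(experiment_id, disease, pair_index, label_on_case,
             protein_group_id, peptide_id, heavy_area, light_area,
             is_depleted_target, is_defunct, stringsAsFactors = FALSE)
}

# Peptide rows for one protein x experiment cell with given case/control
# log2 ratios; heavy/light orientation follows the label assignment.
pep_cell <- function(ratios, protein = "P1", experiment = "CHD_01",
                     disease = "CHD", pair_index = 1L,
                     label_on_case = TRUE, ...) {
  x <- if (label_on_case) 1 else -1
  do.call(rbind, lapply(seq_along(ratios), function(j) {
    pep_row(experiment_id = experiment, disease = disease,
            pair_index = pair_index, label_on_case = label_on_case,
            protein_group_id = protein,
            peptide_id = paste0(protein, "_pep", j),
            heavy_area = 2^(x * ratios[j]), light_area = 1, ...)
  }))
}

# Assemble a protein_ratio_matrix directly from y/w matrices and pair
# metadata (bypasses rollup for unit tests of downstream stages).
make_matrix <- function(y, w = NULL, disease = NULL, x = NULL) {
  if (is.null(w)) w <- matrix(1, nrow(y), ncol(y), dimnames = dimnames(y))
  n <- ncol(y)
  if (is.null(disease)) disease <- rep("CHD", n)
  if (is.null(x)) x <- rep(1L, n)
  if (is.null(colnames(y))) {
    colnames(y) <- paste0(disease, "_", seq_len(n))
    colnames(w) <- colnames(y)
  }
  if (is.null(rownames(y))) {
    rownames(y) <- paste0("P", seq_len(nrow(y)))
    rownames(w) <- rownames(y)
  }
  dimnames(w) <- dimnames(y)
  pairs <- data.frame(experiment_id = colnames(y), disease = disease,
                      pair_index = stats::ave(seq_len(n), disease,
                                              FUN = seq_along),
                      x = as.integer(x), stringsAsFactors = FALSE)
  structure(list(y = y, w = w, pairs = pairs,
                 centering = stats::setNames(rep(NA_real_, n), colnames(y))),
            class = "protein_ratio_matrix")
}

# Independent weighted least-squares oracle: explicit normal equations.
wls_oracle <- function(X, y, w) {
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  res <- y - X %*% beta
  list(beta = drop(beta),
       s2 = sum(w * res^2) / (length(y) - ncol(X)),
       cov_unscaled = solve(XtW %*% X))
}

# Brute-force regularized T2 for m = 2 via the explicit 2x2 inverse.
t2_oracle_2x2 <- function(sub, ridge_frac) {
  n <- ncol(sub)
  ybar <- rowMeans(sub)
  S <- stats::cov(t(sub))
  r <- ridge_frac * mean(diag(S))
  A <- S + diag(r, 2)
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  Ainv <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2) / det
  n * drop(t(ybar) %*% Ainv %*% ybar)
}

path_extdata <- function(file) {
  system.file("extdata", file, package = "poolprot", mustWork = TRUE)
}
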