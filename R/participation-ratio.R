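# Participation-ratio dimensionality of input connectivity.

#' Participation ratio of the input covariance spectrum
#'
#' Effective dimensionality of the input currents a circuit delivers to its
#' output population: for the covariance matrix C of input connectivity
#' (input channels as variables, outputs as observations) with eigenvalues
#' mu_1..mu_M,
#'
#'   PR(C) = (sum mu_i)^2 / sum mu_i^2 = tr(C)^2 / tr(C^2).
#'
#' PR equals M for equal eigenvalues (identity-like covariance), 1 for a
#' rank-1 spectrum, and decreases as connection weight concentrates on a few
#' input channels; it is invariant to input permutation and to overall
#' scaling of the weights. Computed on synapse-weighted connectivity by
#' default, since input currents depend on synaptic weights; set
#' `weighted = FALSE` for the binary-connectivity variant.
#'
#' @param m a `connectivity_matrix` with at least 2 outputs, or a covariance
#'   matrix supplied directly via [participation_ratio_from_cov()].
#' @param weighted logical; use synapse counts (default) or binarized
#'   connectivity.
#' @return list with `pr`, `trace` (tr C), and `trace_sq` (tr C^2).
#' @examples
#' m <- generate_wiring(wiring_spec(n_inputs = 20, n_outputs = 50), seed = 1)
#' participation_ratio(m)$pr
#' @export
participation_ratio <- function(m, weighted = TRUE) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (ncol(m$W) < 2) stop("participation ratio needs at least 2 outputs")
  X <- if (weighted) m$W else binarize(m)$W
  if (all(X == 0)) stop("all-zero connectivity matrix")
  C <- cov(t(X))   # variables = input channels, observations = outputs
  participation_ratio_from_cov(C)
}

#' Participation ratio of a covariance matrix
#'
#' @param C symmetric positive semidefinite covariance matrix.
#' @return list with `pr`, `trace`, `trace_sq`.
#' @rdname participation_ratio
#' @export
participation_ratio_from_cov <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C)))) {
    stop("covariance matrix must be symmetric")
  }
  tr <- sum(diag(C))
  tr2 <- sum(C * C)   # tr(C^2) = Frobenius norm squared for symmetric C
  if (tr2 == 0) stop("zero covariance: participation ratio undefined")
  list(pr = tr^2 / tr2, trace = tr, trace_sq = tr2)
}
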