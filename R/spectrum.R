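# PCA eigenvalue-spectrum test of a connectivity matrix against the
# marginal-preserving shuffle null.

#' Variance fractions of the input-covariance spectrum
#'
#' Treats outputs as observations and input channels as variables, mean
#' centers each input channel, and returns the eigenvalues of the resulting
#' input covariance matrix as fractions of total variance.
#'
#' @param X numeric matrix, inputs x outputs.
#' @return numeric vector of variance fractions (length = number of inputs),
#'   non-increasing, summing to 1. If total variance is zero, the first
#'   fraction is 1 by convention (with a warning).
#' @export
spectrum_fractions <- function(X) {
  stopifnot(is.matrix(X))
  obs <- t(X)                     # outputs are observations
  obs <- sweep(obs, 2, colMeans(obs))
  C <- crossprod(obs) / (nrow(obs) - 1)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  tot <- sum(ev)
  if (tot == 0) {
    warning("zero total variance; degenerate spectrum")
    return(c(1, rep(0, length(ev) - 1)))
  }
  ev / tot
}

#' PCA spectrum test against the shuffle null
#'
#' Compares the fractions of variance explained by the principal components
#' of a connectivity matrix with those obtained from an ensemble of
#' marginal-preserving shuffles. Components whose observed variance fraction
#' falls outside the empirical 95% null band indicate wiring structure
#' beyond what non-uniform input connection probabilities and in-degrees
#' produce; a random-sampling circuit shows none.
#'
#' The covariance is taken over input channels with outputs as observations.
#' By default the matrix is binarized before both the observed and the null
#' spectra (`weighted = TRUE` uses synapse counts instead; the shuffle null
#' is always built on binary connectivity).
#'
#' @param m a `connectivity_matrix` with at least 2 connected outputs.
#' @param cfg a [shuffle_config()].
#' @param weighted logical; use synapse-weighted connectivity for the
#'   observed spectrum.
#' @return an object of class `spectrum_result`: list with
#'   `observed_fractions`, `null_mean`, `null_lo`, `null_hi` (2.5/97.5
#'   percentiles over shuffles), `components_outside` (indices where the
#'   observed fraction leaves the band), and `n_shuffles`.
#' @export
pca_spectrum_test <- function(m, cfg = shuffle_config(), weighted = FALSE) {
  stopifnot(inherits(m, "connectivity_matrix"), inherits(cfg, "shuffle_config"))
  mb <- if (m$binarized) m else binarize(m)
  if (sum(colSums(mb$W) > 0) < 2) {
    stop("spectrum test needs at least 2 outputs with at least 1 input")
  }
  if (nrow(m$W) == 1) {
    warning("single input channel: spectrum is degenerate")
    return(structure(
      list(
        observed_fractions = 1, null_mean = 1, null_lo = 1, null_hi = 1,
        components_outside = integer(0), n_shuffles = cfg$n_shuffles
      ),
      class = "spectrum_result"
    ))
  }
  obs <- spectrum_fractions(if (weighted) m$W else mb$W)
  nulls <- shuffle_ensemble(mb, cfg$n_shuffles, fun = spectrum_fractions,
                            seed = cfg$seed)
  nullmat <- do.call(rbind, nulls)   # shuffles x components
  null_mean <- colMeans(nullmat)
  null_lo <- apply(nullmat, 2, quantile, probs = 0.025, names = FALSE)
  null_hi <- apply(nullmat, 2, quantile, probs = 0.975, names = FALSE)
  outside <- which(obs > null_hi | obs < null_lo)
  structure(
    list(
      observed_fractions = obs, null_mean = null_mean,
      null_lo = null_lo, null_hi = null_hi,
      components_outside = outside, n_shuffles = cfg$n_shuffles
    ),
    class = "spectrum_result"
  )
}

#' @export
print.spectrum_result <- function(x, ...) {
  k <- min(5L, length(x$observed_fractions))
  cat(sprintf(
    "<spectrum_result> %d components, %d shuffles\n",
    length(x$observed_fractions), x$n_shuffles
  ))
  cat("  top fractions (observed | null mean [95% band]):\n")
  for (i in seq_len(k)) {
    cat(sprintf(
      "   PC%d: %.4f | %.4f [%.4f, %.4f]%s\n", i,
      x$observed_fractions[i], x$null_mean[i], x$null_lo[i], x$null_hi[i],
      if (i %in% x$components_outside) " *" else ""
    ))
  }
  cat(sprintf("  components outside the null band: %d\n",
              length(x$components_outside)))
  invisible(x)
}
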