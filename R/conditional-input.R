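# Conditional input analysis: pairwise co-occurrence of inputs on the
# output population, z-scored against the marginal-preserving shuffle null,
# with K-means grouping of inputs by their conditional-input profiles.

#' Conditional input analysis
#'
#' For every pair of inputs (A, B), counts the number of outputs receiving
#' both A and B (each connection counted once regardless of synapse count),
#' builds a null distribution of those counts from marginal-preserving
#' shuffles, and z-scores the observed count against it. Structured wiring
#' (inputs that co-occur on the same outputs more or less than their
#' connection probabilities predict) shows up as large |z|; random sampling
#' gives a calibrated z map. K-means clustering of the z-matrix rows is run
#' over a range of cluster numbers to extract input groupings.
#'
#' @param m a `connectivity_matrix` (binarized internally).
#' @param cfg a [shuffle_config()].
#' @param k_range integer vector of cluster numbers (default 2:10). Values
#'   exceeding the number of inputs minus one are dropped with a warning.
#' @param nstart K-means restarts (default 20).
#' @return an object of class `conditional_input_result`: list with
#'   `count` (symmetric co-occurrence matrix; diagonal = per-input partner
#'   counts), `z` (z-score matrix, 0 where the null sd is 0),
#'   `degenerate` (logical matrix flagging those zero-sd pairs),
#'   `null_mean`, `null_sd`, and `clusterings` (named list of integer label
#'   vectors, one per k).
#' @export
conditional_input_analysis <- function(m, cfg = shuffle_config(),
                                       k_range = 2:10, nstart = 20L) {
  stopifnot(inherits(m, "connectivity_matrix"), inherits(cfg, "shuffle_config"))
  mb <- binarize(m)
  X <- mb$W
  n_in <- nrow(X)
  cooc <- function(B) tcrossprod(B)   # inputs x inputs co-occurrence counts
  count <- cooc(X)

  nulls <- shuffle_ensemble(mb, cfg$n_shuffles, fun = cooc, seed = cfg$seed)
  acc <- matrix(0, n_in, n_in)
  acc2 <- matrix(0, n_in, n_in)
  for (Ni in nulls) {
    acc <- acc + Ni
    acc2 <- acc2 + Ni^2
  }
  null_mean <- acc / cfg$n_shuffles
  null_var <- pmax(acc2 / cfg$n_shuffles - null_mean^2, 0)
  null_sd <- sqrt(null_var)
  degenerate <- null_sd == 0
  z <- matrix(0, n_in, n_in, dimnames = dimnames(count))
  z[!degenerate] <- (count[!degenerate] - null_mean[!degenerate]) /
    null_sd[!degenerate]

  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range >= n_in)) {
    warning("k_range truncated: fewer inputs than requested clusters")
    k_range <- k_range[k_range < n_in]
  }
  n_distinct <- nrow(unique(z))
  clusterings <- with_seed(derive_seed(cfg$seed, "condinput_kmeans"), {
    out <- lapply(k_range, function(k) {
      if (n_distinct <= k) {
        # degenerate: fewer distinct profiles than clusters; group identical
        # rows instead of running K-means
        key <- apply(z, 1, paste, collapse = ",")
        setNames(as.integer(factor(key, levels = unique(key))), rownames(z))
      } else {
        kmeans(z, centers = k, nstart = nstart)$cluster
      }
    })
    names(out) <- paste0("k", k_range)
    out
  })
  structure(
    list(
      count = count, z = z, degenerate = degenerate,
      null_mean = null_mean, null_sd = null_sd, clusterings = clusterings
    ),
    class = "conditional_input_result"
  )
}

#' @export
print.conditional_input_result <- function(x, ...) {
  off <- x$z[upper.tri(x$z)]
  cat(sprintf(
    "<conditional_input_result> %d inputs; off-diagonal |z| > 1.96: %.3f\n",
    nrow(x$z), mean(abs(off) > 1.96)
  ))
  cat(sprintf("  clusterings computed for k in {%s}\n",
              paste(sub("^k", "", names(x$clusterings)), collapse = ", ")))
  invisible(x)
}
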