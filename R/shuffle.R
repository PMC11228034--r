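# Marginal-preserving shuffle null model: the randomness machinery behind
# the spectrum, conditional-input, and bilateral stereotypy tests.

# Internal workhorse. Returns per-output in-degrees and the input marginal
# weights of a binarized matrix, validating that the shuffle is well posed.
shuffle_marginals <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (!m$binarized) {
    message("shuffle operates on binarized connectivity; binarizing input")
    m <- binarize(m)
  }
  X <- m$W
  k <- colSums(X)
  w <- rowSums(X)
  if (sum(w) == 0 && any(k > 0)) {
    stop("all input marginals are zero but outputs demand connections")
  }
  list(m = m, indegree = k, weights = w)
}

#' Marginal-preserving shuffle of a binarized connectivity matrix
#'
#' Re-draws the inputs of every output while fixing (a) the exact per-output
#' in-degree and (b) input connection probabilities, realized by sampling
#' each output's inputs without replacement with probability proportional to
#' the input's connection count (row degree) in the observed matrix. Outputs
#' with in-degree 0 stay empty. Weighted matrices are binarized first with a
#' notice, since the preserved marginals are defined on binary connectivity.
#'
#' @param m a `connectivity_matrix`.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return a binarized `connectivity_matrix` with identical column sums.
#' @export
shuffle_preserving_marginals <- function(m, seed = NULL) {
  mm <- shuffle_marginals(m)
  with_seed(seed, shuffle_once(mm))
}

# One shuffle draw from precomputed marginals; uses the current RNG stream.
shuffle_once <- function(mm) {
  X <- mm$m$W
  n_in <- nrow(X)
  S <- matrix(0, n_in, ncol(X), dimnames = dimnames(X))
  w <- mm$weights
  pos <- which(w > 0)
  wpos <- w[pos]
  for (j in seq_along(mm$indegree)) {
    k <- mm$indegree[j]
    if (k == 0) next
    if (k > length(pos)) stop("in-degree exceeds the number of connectable inputs")
    S[pos[sample.int(length(pos), k, prob = wpos)], j] <- 1
  }
  connectivity_matrix(S, threshold = mm$m$threshold, binarized = TRUE)
}

#' Ensemble of marginal-preserving shuffles
#'
#' Generates `n_shuffles` shuffles of `m` and applies `fun` to each shuffled
#' binary matrix (the raw numeric matrix, not the wrapper), collecting the
#' results in a list. This is the shared engine of the spectrum,
#' conditional-input, and bilateral tests; drawing all shuffles through one
#' seeded stream keeps every test reproducible from `(matrix, seed)`.
#'
#' @param m a `connectivity_matrix`.
#' @param n_shuffles number of shuffles (the null ensembles use 1000).
#' @param fun function applied to each shuffled binary matrix.
#' @param seed integer seed.
#' @return list of `fun` results, length `n_shuffles`.
#' @export
shuffle_ensemble <- function(m, n_shuffles = 1000L, fun = identity, seed = 1L) {
  stopifnot(n_shuffles >= 1)
  mm <- shuffle_marginals(m)
  with_seed(seed, {
    lapply(seq_len(n_shuffles), function(i) fun(shuffle_once(mm)$W))
  })
}

#' Shuffle-test configuration
#'
#' @param n_shuffles number of random shuffles in the null ensemble
#'   (default 1000).
#' @param seed integer seed.
#' @param mode null model for bilateral comparisons: `"independent"`
#'   (each hemisphere reshuffled independently) or `"mirrored"` (one
#'   hemisphere shuffled and copied to the other: random but identical on
#'   both sides).
#' @return a `shuffle_config` list.
#' @export
shuffle_config <- function(n_shuffles = 1000L, seed = 1L,
                           mode = c("independent", "mirrored")) {
  mode <- match.arg(mode)
  stopifnot(n_shuffles >= 1)
  structure(
    list(n_shuffles = as.integer(n_shuffles), seed = as.integer(seed), mode = mode),
    class = "shuffle_config"
  )
}
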