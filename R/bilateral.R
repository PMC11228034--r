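# Bilateral stereotypy: do outputs on the left have a counterpart on the
# right receiving the identical set of input types, more often than chance?

# Expand a type-aggregated binary matrix to a common (sorted) label space,
# inserting all-zero rows for types absent on one side.
expand_to_labels <- function(X, labels) {
  out <- matrix(0, length(labels), ncol(X),
                dimnames = list(labels, colnames(X)))
  out[rownames(X), ] <- X
  out
}

# Count left outputs (with >= 1 input) whose exact binary input pattern
# occurs among the right outputs. Patterns are compared via a fixed random
# projection: identical columns give bitwise-identical keys, and distinct
# binary patterns collide with probability 0 in double precision.
match_count <- function(XL, XR, proj) {
  kL <- as.vector(crossprod(XL, proj))
  kR <- as.vector(crossprod(XR, proj))
  eligible <- colSums(XL) > 0
  sum(kL[eligible] %in% kR[colSums(XR) > 0])
}

#' Bilateral identical-input-pattern stereotypy test
#'
#' Counts how many outputs in the left hemisphere receive exactly the same
#' set of input types as at least one output in the right hemisphere, and
#' compares that count to a null ensemble of marginal-preserving shuffles.
#' Each left output counts at most once no matter how many right outputs it
#' matches, and outputs receiving no input are not counted (nor matchable).
#'
#' Both matrices are binarized and aggregated to input types through `tmap`
#' (a type connects to an output if any of its member neurons does) before
#' comparison, so that the left/right pairing is by homologous type rather
#' than by individual neuron identity.
#'
#' The null is built per `cfg$mode`: `"independent"` reshuffles both sides
#' independently (random, non-stereotyped wiring); `"mirrored"` shuffles the
#' left side and copies the shuffled pattern set to the right (random but
#' identical in each hemisphere), which bounds the counts attainable under
#' perfect stereotypy.
#'
#' @param left,right `connectivity_matrix` objects for the two hemispheres.
#' @param tmap named character vector mapping every input id of both
#'   matrices to a shared type label.
#' @param cfg a [shuffle_config()].
#' @return an object of class `bilateral_result`: list with
#'   `observed_count`, `null_counts` (length `cfg$n_shuffles`), `p_value`
#'   (fraction of null >= observed, with the (r+1)/(n+1) correction),
#'   `n_eligible` (left outputs with >= 1 input), and `mode`.
#' @export
bilateral_identity_test <- function(left, right, tmap, cfg = shuffle_config()) {
  stopifnot(inherits(left, "connectivity_matrix"),
            inherits(right, "connectivity_matrix"),
            inherits(cfg, "shuffle_config"))
  agg <- function(m) {
    mb <- binarize(m)
    a <- aggregate_by_type(mb, tmap, mode = "sum")
    (a$W > 0) + 0
  }
  XL <- agg(left)
  XR <- agg(right)
  if (length(intersect(rownames(XL), rownames(XR))) == 0) {
    stop("left and right share no input types after mapping")
  }
  labels <- sort(union(rownames(XL), rownames(XR)))
  XL <- expand_to_labels(XL, labels)
  XR <- expand_to_labels(XR, labels)

  mkL <- shuffle_marginals(connectivity_matrix(XL, binarized = TRUE))
  mkR <- shuffle_marginals(connectivity_matrix(XR, binarized = TRUE))

  res <- with_seed(cfg$seed, {
    proj <- rnorm(length(labels))
    observed <- match_count(XL, XR, proj)
    null_counts <- vapply(seq_len(cfg$n_shuffles), function(i) {
      SL <- shuffle_once(mkL)$W
      SR <- if (cfg$mode == "mirrored") SL else shuffle_once(mkR)$W
      match_count(SL, SR, proj)
    }, numeric(1))
    list(observed = observed, null = null_counts)
  })
  p <- (sum(res$null >= res$observed) + 1) / (cfg$n_shuffles + 1)
  structure(
    list(
      observed_count = res$observed, null_counts = res$null, p_value = p,
      n_eligible = sum(colSums(XL) > 0), mode = cfg$mode
    ),
    class = "bilateral_result"
  )
}

#' @export
print.bilateral_result <- function(x, ...) {
  cat(sprintf(
    "<bilateral_result> %d / %d left outputs with an identical right pattern\n",
    x$observed_count, x$n_eligible
  ))
  cat(sprintf(
    "  null (%s, n = %d): mean %.2f [%.0f, %.0f]; p = %.4g\n",
    x$mode, length(x$null_counts), mean(x$null_counts),
    quantile(x$null_counts, 0.025), quantile(x$null_counts, 0.975), x$p_value
  ))
  invisible(x)
}
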