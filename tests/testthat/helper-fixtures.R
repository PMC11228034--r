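# Shared fixtures and independent oracles for the test suite.

# Tiny edge list with a threshold-straddling pair.
tiny_edges <- function() {
  data.frame(
    pre_id = c("A", "A", "B"),
    post_id = c("K1", "K2", "K2"),
    count = c(6, 9, 5)
  )
}

jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# Exact inclusion probabilities for successive weighted sampling without
# replacement of k items from weights w (enumeration over ordered draws).
# Independent oracle for the shuffle's input-marginal law.
inclusion_probs <- function(w, k) {
  n <- length(w)
  p <- numeric(n)
  rec <- function(avail, k_left, prob) {
    if (k_left == 0) return(invisible())
    tot <- sum(w[avail])
    for (j in avail) {
      pj <- prob * w[j] / tot
      p[j] <<- p[j] + pj
      rec(setdiff(avail, j), k_left - 1, pj)
    }
  }
  rec(which(w > 0), k, 1)
  p
}

# Brute-force pairwise co-occurrence loop (oracle for the matrix-product
# conditional-input count).
brute_cooccurrence <- function(X) {
  n <- nrow(X)
  out <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      out[a, b] <- sum(X[a, ] > 0 & X[b, ] > 0)
    }
  }
  out
}

# Agreement of two labelings up to relabeling (adjusted Rand index).
label_agreement <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    mclust::adjustedRandIndex(a, b)
  } else {
    # contingency-based ARI, direct from the definition
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sum_ij <- sum(comb2(tab))
    sum_a <- sum(comb2(rowSums(tab)))
    sum_b <- sum(comb2(colSums(tab)))
    n2 <- comb2(sum(tab))
    exp_idx <- sum_a * sum_b / n2
    (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
  }
}

# Uniformly distributed unit vectors (for equal-area checks).
runif_sphere <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}
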