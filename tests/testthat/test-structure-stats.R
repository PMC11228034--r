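test_that("participation ratio matches closed forms on known spectra", {
  expect_equal(participation_ratio_from_cov(diag(10))$pr, 10)
  # rank-1 covariance
  v <- c(3, 1, 2)
  expect_equal(participation_ratio_from_cov(outer(v, v))$pr, 1)
  # eigenvalues (2, 1, 1): PR = (2+1+1)^2 / (4+1+1) = 16/6
  expect_equal(participation_ratio_from_cov(diag(c(2, 1, 1)))$pr, 16 / 6)
})

test_that("participation ratio is scale- and permutation-invariant", {
  m <- generate_wiring(wiring_spec(n_inputs = 15, n_outputs = 40), seed = 3)
  pr0 <- participation_ratio(m)$pr
  W3 <- m$W * 3
  m3 <- connectivity_matrix(W3, threshold = m$threshold)
  expect_equal(participation_ratio(m3)$pr, pr0, tolerance = 1e-12)
  perm <- sample(nrow(m$W))
  mp <- connectivity_matrix(m$W[perm, ], threshold = m$threshold)
  expect_equal(participation_ratio(mp)$pr, pr0, tolerance = 1e-12)
  expect_true(pr0 >= 1)
})

test_that("concentrating spectral mass lowers the participation ratio", {
  # mean-preserving spreads of the eigenvalue distribution reduce PR
  flat <- participation_ratio_from_cov(diag(c(1, 1, 1, 1)))$pr
  skew <- participation_ratio_from_cov(diag(c(2, 1, 0.5, 0.5)))$pr
  spike <- participation_ratio_from_cov(diag(c(3.5, 0.25, 0.15, 0.1)))$pr
  expect_gt(flat, skew)
  expect_gt(skew, spike)
})

test_that("co-occurrence counts equal the brute-force pairwise loop", {
  m <- binarize(generate_wiring(wiring_spec(n_inputs = 12, n_outputs = 30),
                                seed = 5))
  ci <- conditional_input_analysis(m, shuffle_config(20, seed = 6),
                                   k_range = 2:3)
  expect_equal(ci$count, brute_cooccurrence(m$W))
  expect_equal(diag(ci$count), rowSums(m$W > 0))
  expect_equal(ci$count, t(ci$count))
})

test_that("degenerate null pairs get z = 0 and a flag", {
  # all-ones matrix: every shuffle identical, null sd 0 everywhere
  W <- matrix(1, 4, 8, dimnames = list(paste0("i", 1:4), paste0("o", 1:8)))
  m <- connectivity_matrix(W, binarized = TRUE)
  ci <- conditional_input_analysis(m, shuffle_config(30, seed = 1),
                                   k_range = 2:3)
  expect_true(all(ci$degenerate))
  expect_true(all(ci$z == 0))
})

test_that("labelled-line wiring shows block-signed z and K-means recovery", {
  ll <- generate_wiring(
    wiring_spec(n_inputs = 24, n_outputs = 72, model = "labeled_line",
                n_communities = 4, noise = 0, indegree_dist = c(2, 3, 4)),
    seed = 7
  )
  ci <- conditional_input_analysis(ll, shuffle_config(500, seed = 8),
                                   k_range = 2:6)
  comm <- attr(ll, "input_community")
  same <- outer(comm, comm, `==`) & upper.tri(ci$z)
  cross <- outer(comm, comm, `!=`) & upper.tri(ci$z)
  expect_gt(mean(ci$z[same]), 1)
  expect_lt(mean(ci$z[cross]), 0)
  expect_gte(label_agreement(ci$clusterings$k4, comm), 0.9)
})

test_that("k_range is truncated when inputs are scarce", {
  m <- binarize(generate_wiring(
    wiring_spec(n_inputs = 5, n_outputs = 30, indegree_dist = c(1, 2)),
    seed = 9
  ))
  expect_warning(
    ci <- conditional_input_analysis(m, shuffle_config(20, seed = 1),
                                     k_range = 2:10),
    "truncated"
  )
  expect_equal(names(ci$clusterings), paste0("k", 2:4))
})

test_that("planted 4-block connectivity selects k = 4 with matching labels", {
  ll <- generate_wiring(
    wiring_spec(n_inputs = 24, n_outputs = 72, model = "labeled_line",
                n_communities = 4, noise = 0, indegree_dist = c(3, 4, 5)),
    seed = 10
  )
  cl <- cluster_outputs(ll, k_range = 2:8, seed = 11)
  expect_equal(cl$selected_k, 4L)
  expect_false(cl$no_clear_structure)
  oc <- attr(ll, "output_community")
  keep <- !is.na(cl$labels)
  expect_gte(label_agreement(cl$labels[keep], oc[keep]), 0.9)
})

test_that("random wiring is flagged as showing no clear cluster structure", {
  m <- generate_wiring(wiring_spec(n_inputs = 40, n_outputs = 80), seed = 12)
  cl <- cluster_outputs(m, k_range = 2:8, seed = 13)
  expect_true(cl$no_clear_structure)
  expect_lt(cl$profile_silhouette, 0.25)
})

test_that("output clustering is invariant to row permutation up to relabeling", {
  ll <- generate_wiring(
    wiring_spec(n_inputs = 24, n_outputs = 48, model = "labeled_line",
                n_communities = 3, noise = 0, indegree_dist = c(2, 3)),
    seed = 14
  )
  cl1 <- cluster_outputs(ll, k_range = 2:5, seed = 15)
  perm <- sample(nrow(ll$W))
  mp <- connectivity_matrix(ll$W[perm, ], threshold = ll$threshold)
  cl2 <- cluster_outputs(mp, k_range = 2:5, seed = 15)
  expect_equal(cl1$selected_k, cl2$selected_k)
  keep <- !is.na(cl1$labels)
  expect_gte(label_agreement(cl1$labels[keep], cl2$labels[keep]), 0.99)
})
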