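test_that("fixed in-degree wiring gives exactly k inputs per output", {
  spec <- wiring_spec(n_inputs = 10, n_outputs = 25, indegree_dist = 3)
  m <- generate_wiring(spec, seed = 4)
  expect_true(all(colSums(m$W > 0) == 3))
  expect_true(all(m$W[m$W > 0] >= spec$threshold))
})

test_that("degenerate input probabilities route all outputs to one input", {
  p <- c(1, rep(0, 9))
  spec <- wiring_spec(n_inputs = 10, n_outputs = 15, input_probs = p,
                      indegree_dist = 1)
  m <- generate_wiring(spec, seed = 2)
  expect_true(all(m$W[1, ] > 0))
  expect_true(all(m$W[-1, ] == 0))
})

test_that("empirical input frequencies match uniform probabilities", {
  # 10,000 connection draws; each input's share within 3 binomial SEs
  n_in <- 20
  spec <- wiring_spec(n_inputs = n_in, n_outputs = 10000,
                      input_probs = rep(1 / n_in, n_in), indegree_dist = 1)
  m <- generate_wiring(spec, seed = 8)
  freq <- rowSums(m$W > 0)
  p <- 1 / n_in
  se <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(freq - 10000 * p) <= 3 * se))
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- wiring_spec(n_inputs = 12, n_outputs = 30)
  expect_equal(generate_wiring(spec, seed = 5)$W,
               generate_wiring(spec, seed = 5)$W)
  expect_false(identical(generate_wiring(spec, seed = 5)$W,
                         generate_wiring(spec, seed = 6)$W))
  p1 <- generate_bilateral_pair(spec, "mirrored", seed = 9)
  p2 <- generate_bilateral_pair(spec, "mirrored", seed = 9)
  expect_equal(p1$left$W, p2$left$W)
  expect_equal(p1$right$W, p2$right$W)
})

test_that("mirrored pairs are identical under the type map, independent are not", {
  spec <- wiring_spec(n_inputs = 30, n_outputs = 60)
  mir <- generate_bilateral_pair(spec, "mirrored", seed = 3)
  expect_equal(unname(mir$left$W), unname(mir$right$W))
  expect_equal(unname(mir$tmap[input_ids(mir$left)]),
               unname(mir$tmap[input_ids(mir$right)]))
  ind <- generate_bilateral_pair(spec, "independent", seed = 3)
  expect_false(identical(unname(ind$left$W), unname(ind$right$W)))
})

test_that("labelled-line wiring respects communities at zero noise", {
  spec <- wiring_spec(n_inputs = 20, n_outputs = 40, model = "labeled_line",
                      n_communities = 4, noise = 0, indegree_dist = c(1, 2, 3))
  m <- generate_wiring(spec, seed = 6)
  ic <- attr(m, "input_community")
  oc <- attr(m, "output_community")
  for (j in seq_len(ncol(m$W))) {
    used <- which(m$W[, j] > 0)
    expect_true(all(ic[used] == oc[j]))
  }
  # in-degree above community size is impossible
  bad <- wiring_spec(n_inputs = 8, n_outputs = 4, model = "labeled_line",
                     n_communities = 4, indegree_dist = 5)
  expect_error(generate_wiring(bad, seed = 1), "community")
})

test_that("synapse clouds have the prescribed dispersion geometry", {
  expect_equal(
    dispersion_statistic(generate_synapse_cloud("bouton_claw", n_synapses = 1,
                                                seed = 1)),
    0
  )
  # uniform segment of length L: population variance of |x - centroid| -> L^2/48
  L <- 8000
  pts <- generate_synapse_cloud("en_passant", n_synapses = 10000, scale = L,
                                jitter_sd = 0, seed = 2)
  expect_equal(dispersion_statistic(pts), L^2 / 48, tolerance = 0.05)
})

test_that("bouton clouds are more compact than en-passant clouds", {
  # sigma << L/sqrt(48): bouton dispersion below en-passant in every rep
  L <- 10000
  wins <- vapply(1:20, function(i) {
    b <- dispersion_statistic(
      generate_synapse_cloud("bouton_claw", 20, scale = L / 20, seed = 100 + i)
    )
    e <- dispersion_statistic(
      generate_synapse_cloud("en_passant", 20, scale = L, seed = 200 + i)
    )
    b < e
  }, logical(1))
  expect_true(mean(wins) > 0.99)
})

test_that("synthetic visual systems plant recoverable receptive fields", {
  eye <- make_hex_eyemap(n_columns = 361)
  expect_equal(sqrt(rowSums(eye$directions^2)),
               setNames(rep(1, 361), eye$column_ids), tolerance = 1e-9)
  specs <- list(
    list(neuron_id = "V1", center = eye$column_ids[1], n_columns = 20),
    list(neuron_id = "V2", center = eye$column_ids[50], n_columns = 35)
  )
  vs <- generate_visual_system(eye, specs, seed = 7)
  for (id in names(vs$skeletons)) {
    covered <- covered_columns(vs$skeletons[[id]], eye, vs$layer,
                               vs$threshold_nm)
    expect_gte(jaccard(covered, vs$planted_rfs[[id]]), 0.9)
  }
  vs2 <- generate_visual_system(eye, specs, seed = 7)
  expect_equal(vs$skeletons, vs2$skeletons)
  expect_error(
    generate_visual_system(eye, list(list(neuron_id = "x", center = "C9999",
                                          n_columns = 5))),
    "outside"
  )
})
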