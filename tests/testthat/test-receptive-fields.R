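test_that("column coverage follows the distance threshold exactly", {
  eye <- make_hex_eyemap(n_columns = 61)
  mk <- eye$markers$Me
  # a point on a marker is covered at any positive threshold
  expect_equal(covered_columns(mk[5, , drop = FALSE], eye, "Me", 1),
               eye$column_ids[5])
  # threshold 0 keeps exact coincidences only
  expect_equal(covered_columns(mk[c(2, 9), ], eye, "Me", 0),
               sort(eye$column_ids[c(2, 9)]))
  expect_warning(out <- covered_columns(mk[0, , drop = FALSE], eye, "Me", 100),
                 "empty")
  expect_equal(out, character(0))
})

test_that("coverage is monotone in the threshold for every skeleton", {
  eye <- make_hex_eyemap(n_columns = 169)
  vs <- generate_visual_system(
    eye,
    list(list(neuron_id = "V1", center = eye$column_ids[10], n_columns = 15)),
    seed = 3
  )
  pts <- vs$skeletons$V1
  thresholds <- c(500, 1500, 2500, 4000, 8000)
  covs <- lapply(thresholds, function(t) covered_columns(pts, eye, "Me", t))
  for (i in seq_len(length(covs) - 1)) {
    expect_true(all(covs[[i]] %in% covs[[i + 1]]))
  }
})

test_that("receptive-field hulls behave on degenerate and full inputs", {
  eye <- make_hex_eyemap()  # default 759 columns
  one <- rf_from_columns(eye$column_ids[1], eye)
  expect_equal(one$size, 1)
  expect_equal(unname(one$centroid), unname(eye$directions[1, ]),
               tolerance = 1e-9)

  tri <- rf_from_columns(eye$column_ids[c(1, 30, 200)], eye)
  expect_true(all(eye$column_ids[c(1, 30, 200)] %in% tri$hull_columns))
  expect_gte(tri$size, 3)

  full <- rf_from_columns(eye$column_ids, eye)
  expect_equal(full$size, 759)
  expect_true(all(full$covered %in% full$hull_columns))
})

test_that("hulls of compact sets do not leak outside their neighbourhood", {
  eye <- make_hex_eyemap(n_columns = 361)
  vs <- generate_visual_system(
    eye,
    list(list(neuron_id = "V1", center = eye$column_ids[1], n_columns = 25)),
    seed = 4
  )
  rf <- rf_from_columns(vs$planted_rfs$V1, eye)
  expect_true(all(vs$planted_rfs$V1 %in% rf$hull_columns))
  # a compact planted disc is nearly convex: the hull adds few columns
  expect_lte(rf$size, 40)
})

test_that("wide-span covered sets are rejected for the spherical hull", {
  eye <- make_hex_eyemap(n_columns = 200, pitch_deg = 11)
  # two near-antipodal edge columns of the patch: span ~ 160 degrees
  a <- which.min(eye$directions[, 2])
  b <- which.min(as.vector(eye$directions %*% eye$directions[a, ]))
  span <- acos(sum(eye$directions[a, ] * eye$directions[b, ])) * 180 / pi
  expect_gt(span, 150)
  expect_error(rf_from_columns(eye$column_ids[c(a, b)], eye), "150 degrees")
})

test_that("threshold calibration recovers the planted construction threshold", {
  eye <- make_hex_eyemap(n_columns = 271)
  specs <- lapply(1:4, function(i) {
    list(neuron_id = paste0("V", i), center = eye$column_ids[15 * i],
         n_columns = 12 + 3 * i)
  })
  vs <- generate_visual_system(eye, specs, seed = 5)
  gt <- lapply(names(vs$skeletons), function(id) {
    list(points = vs$skeletons[[id]], columns = vs$planted_rfs[[id]])
  })
  grid <- seq(500, 6000, by = 250)
  cal <- calibrate_rf_threshold(gt, eye, "Me", grid = grid)
  expect_gte(cal$mean_jaccard, 0.9)
  # the selected threshold is a global grid maximum (>= both neighbours)
  i <- which(grid == cal$threshold_nm)
  neighbours <- cal$grid_jaccard[c(max(1, i - 1), min(length(grid), i + 1))]
  expect_true(all(cal$mean_jaccard >= neighbours))
  # one-point grids return their value
  expect_equal(calibrate_rf_threshold(gt, eye, "Me", grid = 3000)$threshold_nm,
               3000)
})

test_that("skeletons sitting on their markers select the smallest threshold", {
  eye <- make_hex_eyemap(n_columns = 61)
  cols <- eye$column_ids[1:6]
  gt <- list(list(points = eye$markers$Me[cols, ], columns = cols))
  cal <- calibrate_rf_threshold(gt, eye, "Me", grid = c(0, 100, 1000))
  expect_equal(cal$threshold_nm, 0)
  expect_equal(cal$mean_jaccard, 1)
})

test_that("Mollweide projection hits its analytic anchor points", {
  R <- 1
  anchors <- rbind(
    c(1, 0, 0),    # lat 0, lon 0 -> (0, 0)
    c(0, 0, 1),    # north pole -> (0, sqrt(2))
    c(0, 0, -1),   # south pole -> (0, -sqrt(2))
    c(0, 1, 0)     # lat 0, lon pi/2 -> (sqrt(2), 0): theta = 0 on equator
  )
  xy <- mollweide_project(anchors, R = R, tol = 1e-14)
  expect_equal(xy[1, ], c(x = 0, y = 0), tolerance = 1e-9)
  expect_equal(xy[2, ], c(x = 0, y = sqrt(2)), tolerance = 1e-9)
  expect_equal(xy[3, ], c(x = 0, y = -sqrt(2)), tolerance = 1e-9)
  expect_equal(xy[4, ], c(x = sqrt(2), y = 0), tolerance = 1e-9)
  expect_error(mollweide_project(rbind(c(1, 1, 0))), "unit")
})

test_that("Mollweide is equal-area: uniform directions fill the map uniformly", {
  set.seed(41)
  xy <- mollweide_project(runif_sphere(20000))
  # map ellipse semi-axes a = 2*sqrt(2), b = sqrt(2); uniform density on the
  # sphere must be uniform on the ellipse, so the concentric sub-ellipse of
  # linear scale c holds a fraction c^2 of the points
  a <- 2 * sqrt(2); b <- sqrt(2)
  r2 <- (xy[, 1] / a)^2 + (xy[, 2] / b)^2
  for (cc in c(0.4, 0.6, 0.8)) {
    expect_lt(abs(mean(r2 < cc^2) - cc^2), 0.02)
  }
  expect_lt(abs(mean(xy[, 2] > 0) - 0.5), 0.02)
})

test_that("effective fields combine weighted hull indicators", {
  eye <- make_hex_eyemap(n_columns = 169)
  # two compact, well-separated column discs -> disjoint hulls
  nearest <- function(center_id, n) {
    cosang <- as.vector(eye$directions %*% eye$directions[center_id, ])
    eye$column_ids[order(-cosang)[1:n]]
  }
  left_c <- which.min(eye$directions[, 2])
  right_c <- which.max(eye$directions[, 2])
  rf1 <- rf_from_columns(nearest(left_c, 7), eye)
  rf2 <- rf_from_columns(nearest(right_c, 7), eye)
  expect_length(intersect(rf1$hull_columns, rf2$hull_columns), 0)
  W <- matrix(c(3, 0), 2, 1, dimnames = list(c("V1", "V2"), "K1"))
  dm <- connectivity_matrix(W, threshold = 0)
  f <- effective_rf("K1", dm, rfs = list(V1 = rf1, V2 = rf2), eye = eye)
  expect_equal(unname(f$direct[rf1$hull_columns]),
               rep(3, length(rf1$hull_columns)))
  expect_equal(sum(f$direct > 0), length(rf1$hull_columns))
  expect_true(all(f$indirect == 0))

  # two disjoint equal-weight RFs: equal field on both supports
  W2 <- matrix(c(2, 2), 2, 1, dimnames = list(c("V1", "V2"), "K1"))
  dm2 <- connectivity_matrix(W2, threshold = 0)
  f2 <- effective_rf("K1", dm2, rfs = list(V1 = rf1, V2 = rf2), eye = eye)
  expect_equal(unique(f2$direct[f2$direct > 0]), 2)

  fn <- effective_rf("K1", dm2, rfs = list(V1 = rf1, V2 = rf2), eye = eye,
                     normalize = TRUE)
  expect_equal(sum(fn$direct), 1, tolerance = 1e-12)

  # indirect route: VPN -> LVIN -> KC with per-LVIN normalization
  Wl <- matrix(4, 1, 1, dimnames = list("L1", "K1"))
  Wvl <- matrix(c(1, 1), 2, 1, dimnames = list(c("V1", "V2"), "L1"))
  f3 <- effective_rf("K1", dm2,
                     lvin_matrix = connectivity_matrix(Wl, threshold = 0),
                     vpn_to_lvin_matrix = connectivity_matrix(Wvl, threshold = 0),
                     rfs = list(V1 = rf1, V2 = rf2), eye = eye)
  expect_equal(sum(f3$indirect), 4, tolerance = 1e-12)

  # a cell with no visual inputs yields empty fields with a notice
  W0 <- matrix(0, 2, 1, dimnames = list(c("V1", "V2"), "K9"))
  expect_message(
    f0 <- effective_rf("K9", connectivity_matrix(W0, threshold = 0),
                       rfs = list(V1 = rf1, V2 = rf2), eye = eye),
    "no visual inputs"
  )
  expect_true(all(f0$direct == 0) && all(f0$indirect == 0))
})

test_that("RF size correlates with synapse weight on a planted fixture", {
  # Pearson statistic equals the brute-force covariance computation
  sizes <- c(10, 25, 40, 80, 120)
  weights <- c(12, 30, 35, 90, 150)
  r <- cor(sizes, weights)
  brute <- sum((sizes - mean(sizes)) * (weights - mean(weights))) /
    sqrt(sum((sizes - mean(sizes))^2) * sum((weights - mean(weights))^2))
  expect_equal(r, brute, tolerance = 1e-12)
})
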