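test_that("build_matrix applies the synapse threshold per pair", {
  edges <- data.frame(pre_id = c("A", "B"), post_id = "K1", count = c(6, 4))
  m <- build_matrix(edges, inputs = c("A", "B"), outputs = "K1", threshold = 5)
  expect_equal(m$W["A", "K1"], 6)
  expect_equal(m$W["B", "K1"], 0)

  m2 <- build_matrix(tiny_edges(), inputs = c("A", "B"), outputs = c("K1", "K2"),
                     threshold = 5)
  expect_equal(unname(m2$W), rbind(c(6, 9), c(0, 5)))

  empty <- build_matrix(tiny_edges()[0, ], inputs = c("A", "B"),
                        outputs = c("K1", "K2"), threshold = 5)
  expect_true(all(empty$W == 0))
  expect_equal(dim(empty), c(2L, 2L))
})

test_that("build_matrix orders ids lexicographically and rejects duplicates", {
  m <- build_matrix(tiny_edges(), inputs = c("B", "A"), outputs = c("K2", "K1"),
                    threshold = 5)
  expect_equal(input_ids(m), c("A", "B"))
  expect_equal(output_ids(m), c("K1", "K2"))

  dup <- rbind(tiny_edges(), data.frame(pre_id = "A", post_id = "K1", count = 2))
  expect_error(
    build_matrix(dup, inputs = c("A", "B"), outputs = c("K1", "K2")),
    "duplicate"
  )
})

test_that("rebuilding from a written edge list is idempotent", {
  m <- build_matrix(tiny_edges(), inputs = c("A", "B"), outputs = c("K1", "K2"),
                    threshold = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_edges(m, path)
  edges2 <- read_edges(path)
  m2 <- build_matrix(edges2, inputs = input_ids(m), outputs = output_ids(m),
                     threshold = 5)
  expect_equal(m2$W, m$W)
})

test_that("aggregate_by_type combines same-type rows by mean or sum", {
  edges <- data.frame(pre_id = c("a1", "a2"), post_id = "K1", count = c(5, 7))
  m <- build_matrix(edges, inputs = c("a1", "a2"), outputs = "K1", threshold = 5)
  tmap <- c(a1 = "typeA", a2 = "typeA")
  expect_equal(aggregate_by_type(m, tmap, "mean")$W["typeA", "K1"], 6)
  expect_equal(aggregate_by_type(m, tmap, "sum")$W["typeA", "K1"], 12)

  ident <- setNames(input_ids(m), input_ids(m))
  agg <- aggregate_by_type(m, ident, "sum")
  expect_equal(agg$W[input_ids(m), ], m$W[input_ids(m), ])
  expect_error(aggregate_by_type(m, tmap, "max"))
  expect_error(aggregate_by_type(m, c(a1 = "t"), "sum"), "cover")
})

test_that("summarize_inputs reports group fractions, rankings, and coverage", {
  edges <- data.frame(
    pre_id = c("v1", "v1", "v1", "l1"),
    post_id = c("K01", "K02", "K03", "K01"),
    count = c(10, 10, 10, 10)
  )
  outs <- sprintf("K%02d", 1:10)
  m <- build_matrix(edges, inputs = c("v1", "l1"), outputs = outs, threshold = 5)
  s <- summarize_inputs(m, groups = c(v1 = "VPN", l1 = "LVIN"))

  gs <- s$group_summary
  expect_equal(gs$synapse_fraction[gs$group == "LVIN"], 0.25)
  expect_equal(gs$synapse_fraction[gs$group == "VPN"], 0.75)
  expect_equal(sum(gs$synapse_fraction), 1, tolerance = 1e-12)

  # v1 contacts 3 of 10 outputs
  rk <- s$input_ranking
  expect_equal(rk$pct_outputs_contacted[rk$input_id == "v1"], 30)
  expect_equal(rk$input_id[1], "v1")  # ranked by synapse total

  # outputs with no input excluded from composition, count reported
  expect_equal(s$n_outputs_connected, 3L)
  expect_setequal(s$output_composition$output_id, c("K01", "K02", "K03"))
  comp <- as.matrix(s$output_composition[, c("LVIN", "VPN")])
  expect_equal(unname(rowSums(comp)), rep(1, 3), tolerance = 1e-12)

  empty <- connectivity_matrix(
    matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  )
  expect_warning(se <- summarize_inputs(empty, c(a = "g", b = "g")), "empty")
  expect_equal(nrow(se$input_ranking), 0L)
})

test_that("binarize yields 0/1 indicators and is idempotent", {
  m <- build_matrix(tiny_edges(), inputs = c("A", "B"), outputs = c("K1", "K2"),
                    threshold = 5)
  mb <- binarize(m)
  expect_true(all(mb$W %in% c(0, 1)))
  expect_equal(binarize(mb)$W, mb$W)
  expect_equal(mb$W > 0, m$W > 0)
})
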