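band_checks <- function(g, lay, dims, epsilon = NULL) {
  co <- lay$coords
  # coverage: every node exactly once
  expect_setequal(co$name, get_nodes(g)$name)
  expect_equal(nrow(co), nrow(get_nodes(g)))
  bands <- lay$layer_bands
  # monotone stacking and band disjointness
  expect_true(all(diff(bands$lower) > 0))
  if (nrow(bands) > 1) {
    expect_true(all(bands$upper[-nrow(bands)] < bands$lower[-1]))
  }
  vert <- if (dims == 2) co$y else co$z
  for (i in seq_len(nrow(bands))) {
    inlayer <- co$layer_id == bands$layer_id[i]
    expect_true(all(vert[inlayer] >= bands$lower[i] &
                      vert[inlayer] <= bands$upper[i]))
  }
  # no coincident vertices; optional minimum within-layer separation
  expect_false(anyDuplicated(co[, setdiff(names(co), c("name", "layer_id"))]) > 0)
  if (!is.null(epsilon)) {
    for (lid in unique(co$layer_id)) {
      pts <- as.matrix(co[co$layer_id == lid, c("x", "y")])
      if (nrow(pts) > 1) expect_gte(min(stats::dist(pts)), epsilon)
    }
  }
}

test_that("scaled 2D layout follows its closed form", {
  g <- add_layer(mlgraph("g"), "L")
  g <- add_node(g, "a", "L"); g <- add_node(g, "b", "L")
  lay <- layout_scaled(g, 2)
  expect_equal(lay$coords$x, c(0.25, 0.75))
  expect_equal(lay$coords$y, c(0.5, 0.5))
  expect_equal(lay$layer_bands$lower, 0.1)
  expect_equal(lay$layer_bands$upper, 0.9)
})

test_that("scaled 3D layout puts layer i on the plane z = i", {
  g <- demo_graph()
  lay <- layout_scaled(g, 3)
  expect_setequal(unique(lay$coords$z), 1:3)
  for (i in 1:3) {
    expect_true(all(lay$coords$z[lay$coords$layer_id == i] == i))
  }
  # grid spacing is unit and centred
  l2 <- lay$coords[lay$coords$layer_id == 2, ]  # 3 nodes -> 2x2 grid
  expect_equal(sort(unique(l2$x)), c(-0.5, 0.5))
})

test_that("scaled layout is bit-deterministic; random layout is seed-reproducible", {
  g <- random_multilayer(3, 6, 0.2, seed = 5)
  expect_identical(layout_scaled(g, 2), layout_scaled(g, 2))
  expect_identical(layout_scaled(g, 3), layout_scaled(g, 3))
  expect_identical(layout_random(g, 2, seed = 11), layout_random(g, 2, seed = 11))
  expect_false(identical(layout_random(g, 2, seed = 11)$coords,
                         layout_random(g, 2, seed = 12)$coords))
  # the session RNG stream is not consumed
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(layout_random(g, 2, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("both layout kinds satisfy the band invariants on random graphs", {
  for (seed in 1:10) {
    g <- random_multilayer(1 + seed %% 4, 5, 0.2, seed = seed)
    band_checks(g, layout_scaled(g, 2), 2)
    band_checks(g, layout_scaled(g, 3), 3)
    band_checks(g, layout_random(g, 2, seed = seed), 2, epsilon = 0.05)
    band_checks(g, layout_random(g, 3, seed = seed), 3, epsilon = 0.05)
  }
})

test_that("degenerate layout inputs behave as specified", {
  expect_error(layout_scaled(mlgraph("empty"), 2),
               class = "mlgraph_validation_error")
  # empty layers get a band with no points
  g <- add_layer(add_layer(mlgraph("g"), "full"), "empty")
  g <- add_node(g, "a", "full")
  lay <- layout_scaled(g, 2)
  expect_equal(nrow(lay$coords), 1)
  expect_equal(nrow(lay$layer_bands), 2)
  # single node per layer lands inside its band for any seed
  for (seed in c(1, 99)) {
    l <- layout_random(g, 2, seed = seed)
    expect_true(l$coords$y >= 0.1 && l$coords$y <= 0.9)
  }
  expect_error(layout_random(g, 2, seed = "x"), class = "mlgraph_validation_error")
  expect_error(layout_scaled(demo_graph(), 4), class = "mlgraph_validation_error")
})

test_that("an overcrowded band raises a capacity error advising the scaled layout", {
  g <- add_layer(mlgraph("g"), "L")
  for (i in 1:40) g <- add_node(g, sprintf("n%d", i), "L")
  expect_error(layout_random(g, 2, seed = 1, epsilon = 0.5, max_resample = 50),
               class = "mlgraph_capacity_error")
  # the same graph lays out fine deterministically
  expect_equal(nrow(layout_scaled(g, 2)$coords), 40)
})

test_that("rendering writes non-empty files and checks coverage", {
  g <- demo_graph()
  svg <- tempfile(fileext = ".svg")
  render_layout(g, layout_scaled(g, 2), svg)
  expect_true(file.exists(svg) && file.size(svg) > 0)
  expect_match(readLines(svg)[1], "<svg")

  html <- tempfile(fileext = ".html")
  render_layout(g, layout_random(g, 3, seed = 2), html)
  expect_true(file.exists(html) && file.size(html) > 0)
  expect_match(paste(readLines(html), collapse = ""), "polygon")

  # a graph with no edges renders without error
  g0 <- add_node(add_layer(mlgraph("g0"), "L"), "a", "L")
  p0 <- tempfile(fileext = ".svg")
  render_layout(g0, layout_scaled(g0, 2), p0)
  expect_gt(file.size(p0), 0)

  # layout/graph mismatch is a validation error
  other <- add_node(add_layer(mlgraph("other"), "L"), "zzz", "L")
  expect_error(render_layout(g, layout_scaled(other, 2), tempfile()),
               class = "mlgraph_validation_error")
  expect_error(render_layout(g, layout_scaled(g, 2),
                             file.path(tempdir(), "no_dir", "x.svg")),
               class = "mlgraph_io_error")
})
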