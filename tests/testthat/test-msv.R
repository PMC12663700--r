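test_that("Jensen-Shannon distance endpoints and hand value", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(js_distance(p, p), 0)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1)
  # KL arithmetic by hand: JSD((.5,.5),(1,0)) = 0.311278, sqrt = 0.557923
  expect_equal(js_distance(c(0.5, 0.5), c(1, 0)), 0.557923, tolerance = 1e-6)
  expect_equal(js_distance(c(0.5, 0.5), c(1, 0)),
               oracle_js(c(0.5, 0.5), c(1, 0)), tolerance = 1e-12)
  expect_error(js_distance(c(1, 0), c(1, 0, 0)), "length",
               class = "msvdq_metric_error")
  expect_error(js_distance(c(1.2, -0.2), c(0.5, 0.5)), "negative",
               class = "msvdq_metric_error")
  expect_error(js_distance(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1",
               class = "msvdq_metric_error")
})

test_that("js_distance equals the direct-summation oracle on random pairs", {
  set.seed(31)
  for (rep in 1:20) {
    nb <- sample(c(2, 10, 1000), 1)
    p <- random_density(nb); q <- random_density(nb)
    expect_equal(js_distance(p, q), oracle_js(p, q), tolerance = 1e-12)
    expect_equal(js_distance(p, q), js_distance(q, p))
  }
})

test_that("sqrt-JSD satisfies the triangle inequality (metric property)", {
  set.seed(32)
  for (rep in 1:30) {
    nb <- sample(2:12, 1)
    p <- random_density(nb); q <- random_density(nb); r <- random_density(nb)
    expect_lte(js_distance(p, r),
               js_distance(p, q) + js_distance(q, r) + 1e-12)
  }
})

test_that("pairwise distance matrices are symmetric with the right zeros", {
  u <- c(0.5, 0.5, 0); v <- c(0, 0, 1)
  D <- pairwise_distances(list(a = u, b = u))
  expect_equal(unclass(D), matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                           c("a", "b"))))
  D3 <- pairwise_distances(list(a = u, b = u, c = v))
  expect_equal(sort(D3[upper.tri(D3)]), c(0, 1, 1))
  expect_equal(unclass(D3), t(unclass(D3)))
  expect_error(pairwise_distances(list(a = u)), ">= 2",
               class = "msvdq_metric_error")
})

test_that("simplex embedding reproduces closed-form geometries", {
  # two sources at distance 1: vertices at +/- 0.5, centroid 0
  D2 <- matrix(c(0, 1, 1, 0), 2)
  e2 <- embed_simplex(D2)
  expect_equal(sort(unname(e2$coords[, 1L])), c(-0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(unname(e2$centroid), 0, tolerance = 1e-12)

  # identical sources collapse to the origin
  e0 <- embed_simplex(matrix(0, 3, 3))
  expect_true(all(abs(e0$coords) < 1e-12))

  # four pairwise-disjoint sources: regular tetrahedron, vertex-centroid
  # distance sqrt(3/8)
  D4 <- 1 - diag(4)
  e4 <- embed_simplex(D4)
  d <- sqrt(rowSums(sweep(e4$coords, 2, e4$centroid)^2))
  expect_equal(unname(d), rep(sqrt(3 / 8), 4), tolerance = 1e-10)
})

test_that("embedding reproduces random sqrt-JSD matrices within 1e-8", {
  set.seed(33)
  for (rep in 1:10) {
    s <- sample(3:6, 1)
    dens <- replicate(s, random_density(20), simplify = FALSE)
    names(dens) <- paste0("s", 1:s)
    D <- pairwise_distances(dens)
    e <- embed_simplex(D)
    recon <- as.matrix(stats::dist(e$coords))
    expect_lt(max(abs(recon - unclass(D))), 1e-8)
  }
})

test_that("strongly non-Euclidean distance input is rejected", {
  D <- matrix(c(0, 0.1, 1,
                0.1, 0, 0.1,
                1, 0.1, 0), 3)  # gross triangle violation
  expect_error(embed_simplex(D), "non-Euclidean",
               class = "msvdq_metric_error")
})

test_that("GPD/SPO endpoints match the stated contract", {
  # identical sources: everything 0
  same <- lapply(1:4, function(i) c(0.25, 0.25, 0.5))
  names(same) <- paste0("s", 1:4)
  m0 <- msv(same)
  expect_equal(m0$gpd, 0)
  expect_equal(unname(m0$spo), rep(0, 4))

  # two disjoint equal-weight sources: SPO = 1, 1 and GPD = 1
  m2 <- msv(list(a = c(1, 0), b = c(0, 1)))
  expect_equal(m2$gpd, 1, tolerance = 1e-9)
  expect_equal(unname(m2$spo), c(1, 1), tolerance = 1e-9)

  # four disjoint equal-weight sources: GPD = 1 via the regular simplex
  onehot <- lapply(1:4, function(i) replace(rep(0, 4), i, 1))
  names(onehot) <- paste0("s", 1:4)
  m4 <- msv(onehot)
  expect_equal(m4$gpd, 1, tolerance = 1e-9)
  expect_equal(unname(m4$spo), rep(1, 4), tolerance = 1e-9)
})

test_that("GPD is invariant under relabeling and bin permutation", {
  set.seed(34)
  dens <- replicate(4, random_density(30), simplify = FALSE)
  names(dens) <- paste0("s", 1:4)
  w <- c(10, 20, 30, 40)
  g1 <- msv(dens, weights = w)$gpd
  # relabel/reorder sources (with matching weights)
  perm <- c(3, 1, 4, 2)
  g2 <- msv(dens[perm], weights = w[perm])$gpd
  expect_equal(g1, g2, tolerance = 1e-10)
  # common permutation of histogram bins
  bp <- sample(30L)
  g3 <- msv(lapply(dens, function(p) p[bp]), weights = w)$gpd
  expect_equal(g1, g3, tolerance = 1e-10)
})

test_that("case weights steer the informed centroid", {
  # a heavy source pulls the centroid toward itself, shrinking its SPO
  dens <- list(a = c(1, 0), b = c(0, 1))
  m <- msv(dens, weights = c(9, 1))
  expect_lt(m$spo["a"], m$spo["b"])
  # the light source exceeds c_s and is clipped at 1
  expect_equal(unname(m$spo["b"]), 1)
  expect_true(m$gpd >= 0 && m$gpd <= 1)
})

test_that("MSV plot coordinates and radii follow the embedding", {
  # two sources: one informative axis, second coordinate 0
  e2 <- embed_simplex(matrix(c(0, 0.6, 0.6, 0), 2))
  expect_warning(pc <- msv_plot_coords(e2, dims = 2L), "axes available")
  expect_equal(ncol(pc$coords), 1L)

  # equal weights give equal radii
  m <- msv(list(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1)))
  expect_equal(unname(m$radii), rep(1, 3))

  # three equidistant sources form an equilateral triangle
  D <- matrix(0.2, 3, 3); diag(D) <- 0
  e3 <- embed_simplex(D)
  side <- as.matrix(stats::dist(e3$coords[, 1:2]))
  expect_equal(side[upper.tri(side)], rep(0.2, 3), tolerance = 1e-8)
})

test_that("msv objects print, summarize, plot and coerce", {
  m <- msv(list(a = c(0.5, 0.5), b = c(0.9, 0.1), c = c(0.2, 0.8)),
           weights = c(5, 10, 3))
  expect_output(print(m), "GPD")
  expect_output(summary(m), "Jensen-Shannon")
  cf <- coef(m)
  expect_named(cf, c("gpd", "spo.a", "spo.b", "spo.c"))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(m))
})
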