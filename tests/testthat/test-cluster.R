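test_that("tract distance is a symmetrized mean-closest-point pseudo-metric", {
  set.seed(17)
  a <- apply(matrix(rnorm(30), 10, 3), 2, cumsum)
  b <- apply(matrix(rnorm(30), 10, 3), 2, cumsum)
  expect_lt(tractDistance(a, a), 1e-8)
  expect_equal(tractDistance(a, b), tractDistance(b, a), tolerance = 1e-12)
  expect_gte(tractDistance(a, b), 0)
  # parallel straight tracts offset by 3 mm are exactly 3 mm apart
  s <- cbind(seq(0, 30, length.out = 20), 0, 0)
  expect_equal(tractDistance(s, s + matrix(c(0, 3, 0), 20, 3, TRUE)), 3,
               tolerance = 1e-9)
})

test_that("distances and labels are invariant to rigid rotation", {
  set.seed(23)
  tracts <- lapply(1:8, function(i)
    apply(matrix(rnorm(45), 15, 3), 2, cumsum) +
      matrix(c(ifelse(i <= 4, 0, 40), 0, 0), 15, 3, TRUE))
  ts <- tractSet(tracts)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tsR <- tractSet(lapply(tracts, function(p) p %*% t(R)))
  d1 <- tractAffinity(ts)$distance
  d2 <- tractAffinity(tsR)$distance
  expect_equal(d1, d2, tolerance = 1e-9)
  l1 <- clusterTracts(spectralEmbed(ts), 2L, seed = 4L)
  l2 <- clusterTracts(spectralEmbed(tsR), 2L, seed = 4L)
  expect_gte(clusterPurity(l1, l2), 1)
})

test_that("two well-separated bundles embed separably and cluster purely", {
  set.seed(5)
  mk <- function(offset) lapply(1:10, function(i)
    cbind(seq(0, 25, length.out = 20),
          offset + rnorm(1, sd = 0.5), rnorm(1, sd = 0.5)))
  ts <- tractSet(c(mk(0), mk(30)), labels = rep(1:2, each = 10))
  emb <- spectralEmbed(ts)
  labs <- clusterTracts(emb, 2L, seed = 1L)
  expect_equal(clusterPurity(labs, bundleLabels(ts)), 1)
  # linear separability of the embedding along its first coordinate
  g1 <- emb$coords[1:10, 1]; g2 <- emb$coords[11:20, 1]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))
})

test_that("identical tracts collapse to a point; permutation only relabels", {
  s <- cbind(seq(0, 10, length.out = 12), 2, 1)
  tsSame <- tractSet(lapply(1:5, function(i) s))
  embS <- spectralEmbed(tsSame)
  expect_lt(max(dist(embS$coords)), 1e-8)

  set.seed(8)
  tracts <- lapply(1:6, function(i)
    apply(matrix(rnorm(30), 10, 3), 2, cumsum))
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  e1 <- spectralEmbed(tractSet(tracts))
  e2 <- spectralEmbed(tractSet(tracts[perm]))
  for (c in 1:2)
    expect_equal(abs(e2$coords[, c]), abs(e1$coords[perm, c]),
                 tolerance = 1e-6)
})

test_that("clusterTracts honors k and determinism", {
  set.seed(13)
  coords <- matrix(rnorm(40), 20, 2)
  expect_error(clusterTracts(coords, 0L), "k must be")
  expect_equal(clusterTracts(coords, 1L), rep(1L, 20))
  expect_identical(clusterTracts(coords, 3L, seed = 2L),
                   clusterTracts(coords, 3L, seed = 2L))
})

test_that("purity scores majority agreement", {
  expect_equal(clusterPurity(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(clusterPurity(c(1, 1, 1, 1), c(5, 5, 9, 9)), 0.5)
})
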