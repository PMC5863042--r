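# Thresholded/unweighted and weighted comparator coefficients.

test_that("theta thresholding: high theta empties the network", {
  set.seed(1)
  rho <- random_corr(6, 30)
  net <- threshold_network(rho, theta = 1.01)
  expect_equal(sum(net$adjacency), 0)
  expect_equal(net$degree, rep(0, 6), ignore_attr = TRUE)
  lc <- clustering_unweighted(net)
  expect_false(any(lc$defined))
})

test_that("edge-density thresholding keeps exactly floor(d * N(N-1)/2) top edges", {
  set.seed(2)
  rho <- random_corr(6, 50)
  stopifnot(!anyDuplicated(rho[upper.tri(rho)]))
  net <- threshold_network(rho, edge_density = 0.2)
  m <- floor(0.2 * 6 * 5 / 2)
  expect_equal(sum(net$adjacency) / 2, m)
  # sort-based oracle: the kept edges are the m largest upper-tri values
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  top <- ut[order(-rho[ut])[1:m], , drop = FALSE]
  expect_true(all(net$adjacency[top] == 1))
})

test_that("edge-density ties at the cutoff break in lexicographic (i, j) order", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.9
  # three-way tie at 0.5 spanning the cutoff with floor(0.5 * 6) = 3 edges
  for (p in list(c(1, 3), c(2, 3), c(1, 4))) {
    rho[p[1], p[2]] <- rho[p[2], p[1]] <- 0.5
  }
  rho[2, 4] <- rho[4, 2] <- 0.1
  rho[3, 4] <- rho[4, 3] <- 0.2
  net <- threshold_network(rho, edge_density = 0.5)
  expect_equal(sum(net$adjacency) / 2, 3)
  # (1,3) and (1,4) precede (2,3) lexicographically among the tied entries
  expect_equal(net$adjacency[1, 2], 1)
  expect_equal(net$adjacency[1, 3], 1)
  expect_equal(net$adjacency[1, 4], 1)
  expect_equal(net$adjacency[2, 3], 0)
  expect_error(threshold_network(rho, edge_density = 1.2), "between 0 and 1")
  expect_error(threshold_network(rho), "exactly one")
})

test_that("positive-weight network zeroes negative entries and sums strengths", {
  rho <- matrix(c(
    1, 0.5, -0.3, 0.2,
    0.5, 1, 0.4, -0.6,
    -0.3, 0.4, 1, 0.1,
    0.2, -0.6, 0.1, 1
  ), 4, 4)
  net <- positive_weight_network(rho)
  expect_equal(net$weights[1, 3], 0)
  expect_equal(net$weights[2, 4], 0)
  expect_equal(net$weights[1, 2], 0.5)
  expect_equal(unname(net$strength), c(0.7, 0.9, 0.5, 0.3))

  allneg <- -abs(random_corr(4, 10)); diag(allneg) <- 1
  net0 <- positive_weight_network(allneg)
  expect_equal(sum(net0$weights), 0)
  expect_equal(unname(net0$strength), rep(0, 4))
})

test_that("unweighted clustering: complete graph, star, and brute-force agreement", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  lc <- clustering_unweighted(unweighted_network_for_test(k4))
  expect_equal(lc$values, rep(1, 4))

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  lc <- clustering_unweighted(unweighted_network_for_test(star))
  expect_equal(lc$values[1], 0)
  expect_false(any(lc$defined[2:5]))

  set.seed(12)
  a <- matrix(0, 12, 12)
  a[upper.tri(a)] <- rbinom(66, 1, 0.3)
  a <- a + t(a)
  got <- clustering_unweighted(unweighted_network_for_test(a))
  ora <- oracle_unweighted(a)
  expect_equal(got$values, ora$values, tolerance = 1e-12)
  expect_identical(got$defined, ora$defined)
})

test_that("weighted coefficients reduce to the unweighted one on binary weights", {
  set.seed(13)
  a <- matrix(0, 8, 8)
  a[upper.tri(a)] <- rbinom(28, 1, 0.5)
  a <- a + t(a)
  unw <- clustering_unweighted(unweighted_network_for_test(a))
  wnet <- weighted_network_for_test(a)
  for (fn in list(clustering_barrat, clustering_onnela, clustering_zhang)) {
    wc <- fn(wnet)
    expect_equal(wc$values[unw$defined], unw$values[unw$defined],
                 tolerance = 1e-12)
  }
  # uniform weight c: Barrat reduces too (the scale cancels)
  cnet <- weighted_network_for_test(0.37 * a)
  expect_equal(clustering_barrat(cnet)$values[unw$defined],
               unw$values[unw$defined], tolerance = 1e-12)
})

test_that("Onnela and Zhang are invariant under uniform weight rescaling", {
  set.seed(14)
  w <- positive_weight_network(random_corr(7, 15))$weights
  for (fn in list(clustering_onnela, clustering_zhang)) {
    base <- fn(weighted_network_for_test(w))$values
    scaled <- fn(weighted_network_for_test(10 * w))$values
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("Barrat hand evaluation on a weighted triangle", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.4
  w[2, 3] <- w[3, 2] <- 0.6
  # each node of a complete triangle: numerator = s_i, k - 1 = 1 => 1
  lc <- clustering_barrat(weighted_network_for_test(w))
  expect_equal(lc$values, rep(1, 3))
  expect_equal(oracle_barrat(w)$values, rep(1, 3))
})

test_that("weighted coefficients match brute-force oracles on fixed 5-node graphs", {
  set.seed(15)
  for (rep in 1:15) {
    w <- positive_weight_network(random_corr(5, 9))$weights
    net <- weighted_network_for_test(w)
    expect_equal(clustering_barrat(net)$values, oracle_barrat(w)$values,
                 tolerance = 1e-10)
    expect_equal(clustering_onnela(net)$values, oracle_onnela(w)$values,
                 tolerance = 1e-10)
    expect_equal(clustering_zhang(net)$values, oracle_zhang(w)$values,
                 tolerance = 1e-10)
  }
})

test_that("all four coefficients stay in [0, 1]; extremes behave", {
  set.seed(16)
  for (rep in 1:300) {
    n <- sample(4:9, 1)
    rho <- random_corr(n, n + 10)
    wnet <- positive_weight_network(rho)
    unet <- threshold_network(rho, edge_density = 0.4)
    for (lc in list(clustering_unweighted(unet), clustering_barrat(wnet),
                    clustering_onnela(wnet), clustering_zhang(wnet))) {
      vals <- lc$values[lc$defined]
      expect_true(all(vals >= -1e-12 & vals <= 1 + 1e-12))
    }
  }
  # complete uniform-weight network: everything is exactly 1
  w <- matrix(0.4, 5, 5); diag(w) <- 0
  net <- weighted_network_for_test(w)
  expect_equal(clustering_barrat(net)$values, rep(1, 5))
  expect_equal(clustering_onnela(net)$values, rep(1, 5))
  expect_equal(clustering_zhang(net)$values, rep(1, 5))
  # edgeless: everything undefined
  z <- weighted_network_for_test(matrix(0, 5, 5))
  expect_false(any(clustering_onnela(z)$defined))
  expect_false(any(clustering_zhang(z)$defined))
  expect_false(any(clustering_barrat(z)$defined))
})
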