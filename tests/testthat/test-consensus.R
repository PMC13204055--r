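test_that("point-mass groups yield a perfect block consensus", {
  z <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  cm <- bootstrap_kmeans(z, k = 2, B = 20, base_seed = 1)
  same <- outer(rep(1:2, each = 10), rep(1:2, each = 10), `==`)
  expect_true(all(cm$consensus[same] == 1))
  expect_true(all(cm$consensus[!same] == 0))
})

test_that("consensus entries are exact co-cluster / co-sample ratios", {
  set.seed(2)
  z <- matrix(rnorm(60), 30, 2)
  cm <- bootstrap_kmeans(z, k = 3, B = 5, base_seed = 3)
  off <- upper.tri(cm$consensus)
  sampled <- cm$co_sample_counts[off] > 0
  expect_equal(cm$consensus[off][sampled],
               (cm$co_cluster_counts[off] / cm$co_sample_counts[off])[sampled])
  ## with B = 1 every defined entry is 0 or 1
  cm1 <- bootstrap_kmeans(z, k = 3, B = 1, base_seed = 4)
  expect_true(all(cm1$consensus[off][cm1$co_sample_counts[off] > 0] %in% c(0, 1)))
  ## symmetry and unit diagonal
  expect_identical(cm$consensus, t(cm$consensus))
  expect_true(all(diag(cm$consensus) == 1))
  expect_error(bootstrap_kmeans(z, k = 40, B = 2), "more clusters")
})

test_that("well-separated blobs give compact, separated consensus", {
  set.seed(3)
  centers <- matrix(rnorm(5 * 4), 5, 4) * 0
  centers[cbind(1:5, c(1, 2, 3, 4, 1))] <- c(6, 6, 6, 6, -6)
  lab <- rep(1:5, each = 60)
  z <- centers[lab, ] + matrix(rnorm(300 * 4), 300, 4)
  cm <- bootstrap_kmeans(z, k = 5, B = 100, base_seed = 5)
  wb <- within_between(cm, lab)
  expect_gte(wb[["compactness"]], 0.95)
  expect_lt(wb[["separation"]], 0.1)
  expect_gte(ari_bootstrap(cm, consensus_partition(cm, 5)), 0.9)
  expect_gte(adjusted_rand_index(consensus_partition(cm, 5), lab), 0.9)
})

test_that("PAC counts strictly ambiguous entries and widens monotonically", {
  m01 <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3, 3)
  expect_equal(pac(m01), 0)
  u <- matrix(0.5, 4, 4); diag(u) <- 1
  expect_equal(pac(u), 1)

  v <- c(0.05, 0.5, 0.95, 0.5, 0.02, 0.98)
  m <- diag(4)
  m[upper.tri(m)] <- v
  m <- m + t(m) - diag(diag(m))
  expect_equal(pac(m, 0.1, 0.9), 2 / 6)
  expect_error(pac(m, 0.9, 0.1), "smaller")

  set.seed(6)
  for (i in 1:20) {
    r <- matrix(runif(100), 10, 10)
    r <- (r + t(r)) / 2; diag(r) <- 1
    expect_gte(pac(r, 0.05, 0.95), pac(r, 0.2, 0.8))
  }
})

test_that("ARI matches its closed form and behaves at the null", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(1:4, rep(1, 4)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")

  set.seed(7)
  vals <- replicate(100, {
    a <- sample(3, 1000, replace = TRUE)
    b <- sample(4, 1000, replace = TRUE)
    adjusted_rand_index(a, b)
  })
  expect_lt(abs(mean(vals)), 0.01)

  ## agreement with an independent reference implementation
  for (i in 1:20) {
    a <- sample(4, 60, replace = TRUE); b <- sample(3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }

  ## invariance under label permutation
  a <- sample(4, 50, replace = TRUE); b <- sample(3, 50, replace = TRUE)
  relab <- c(3, 1, 4, 2)[a]
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(relab, b))
  expect_equal(adjusted_rand_index(a, a), 1)
})

test_that("within/between metrics average the right pair sets", {
  cons <- matrix(0.1, 6, 6)
  cons[1:3, 1:3] <- 0.9; cons[4:6, 4:6] <- 0.9; diag(cons) <- 1
  wb <- within_between(cons, rep(1:2, each = 3))
  expect_equal(wb[["compactness"]], 0.9)
  expect_equal(wb[["separation"]], 0.1)

  block <- (cons >= 0.9) * 1; diag(block) <- 1
  wb2 <- within_between(block, rep(1:2, each = 3))
  expect_equal(unname(wb2), c(1, 0))

  u <- matrix(0.4, 5, 5); diag(u) <- 1
  expect_equal(unname(within_between(u, c(1, 1, 2, 2, 2))), c(0.4, 0.4))
  expect_error(within_between(u, 1:5), "singleton")
})

test_that("bootstrap ARI matches its reference behaviour", {
  ref <- rep(1:3, each = 10)
  parts <- matrix(ref, 30, 10)
  expect_equal(ari_bootstrap(parts, ref), 1)
  set.seed(8)
  rnd <- matrix(sample(3, 30 * 50, replace = TRUE), 30, 50)
  expect_lt(abs(ari_bootstrap(rnd, sample(3, 30, replace = TRUE))), 0.1)
  expect_error(ari_bootstrap(matrix(integer(0), 5, 0), 1:5), "no replicate")
})

test_that("sum-of-ranks selection follows the metric directions", {
  tab <- data.frame(k = 4:6,
                    compactness = c(0.7, 0.9, 0.6),
                    separation = c(0.2, 0.05, 0.3),
                    pac = c(0.3, 0.1, 0.4),
                    ari_bootstrap = c(0.5, 0.9, 0.4))
  expect_identical(attr(select_k_consensus(tab), "selected_k"), 5L)

  ## K = 5 vs K = 6 with comparable within/between but a markedly lower ARI
  tab2 <- data.frame(k = c(5, 6),
                     compactness = c(0.86, 0.86),
                     separation = c(0.04, 0.04),
                     pac = c(0.28, 0.28),
                     ari_bootstrap = c(0.69, 0.50))
  expect_identical(attr(select_k_consensus(tab2), "selected_k"), 5)

  tie <- data.frame(k = c(4, 7), compactness = 0.8, separation = 0.1,
                    pac = 0.2, ari_bootstrap = 0.7)
  expect_identical(attr(select_k_consensus(tie), "selected_k"), 4)
  expect_error(select_k_consensus(tab[, -3]), "missing metric")
})

test_that("hierarchical aggregation recovers consensus blocks", {
  cons <- matrix(0, 9, 9)
  for (b in 0:2) cons[b * 3 + 1:3, b * 3 + 1:3] <- 1
  labs <- consensus_partition(cons, 3)
  expect_equal(adjusted_rand_index(labs, rep(1:3, each = 3)), 1)
  expect_error(consensus_partition(cons, 1), ">= 2")
  expect_error(consensus_partition(cons, 20), "more groups")

  set.seed(9)
  noisy <- cons * 0.8 + matrix(runif(81, 0, 0.2), 9, 9)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 1
  expect_gte(adjusted_rand_index(consensus_partition(noisy, 3),
                                 rep(1:3, each = 3)), 0.9)
})

test_that("the full consensus stage is reproducible and selects planted K", {
  set.seed(10)
  lab <- rep(1:5, each = 40)
  z <- (diag(5) * 6)[lab, ] + matrix(rnorm(200 * 5), 200, 5)
  c1 <- consensus_cluster(z, k_grid = 4:6, B = 40, base_seed = 11)
  c2 <- consensus_cluster(z, k_grid = 4:6, B = 40, base_seed = 11)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$selected_k, 5L)
  expect_gte(adjusted_rand_index(c1$labels, lab), 0.95)
})
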