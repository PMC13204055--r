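test_that("null clusters produce ~5% raw rejections and calibrated FDR", {
  set.seed(1)
  raw_rej <- fdr_rej <- 0
  n_fac <- 4; reps <- 200
  for (r in seq_len(reps)) {
    z <- matrix(rnorm(120 * n_fac), 120, n_fac)
    lab <- rep(1:3, each = 40)
    pr <- cluster_factor_profiles(z, lab)
    raw_rej <- raw_rej + sum(pr$tests$p < 0.05)
    fdr_rej <- fdr_rej + sum(pr$tests$p_adj < 0.05)
  }
  rate <- raw_rej / (reps * n_fac)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
  expect_lte(fdr_rej, raw_rej)
})

test_that("a planted shift is flagged and detected", {
  set.seed(2)
  z <- matrix(rnorm(300 * 3), 300, 3)
  lab <- rep(1:3, each = 100)
  z[lab == 2, 1] <- z[lab == 2, 1] + 1
  z <- scale(z, scale = FALSE)
  pr <- cluster_factor_profiles(z, lab)
  expect_true(pr$flags[2, 1])
  expect_lt(pr$tests$p_adj[1], 0.05)
})

test_that("identical groups give H = 0 and p = 1", {
  z <- cbind(rep(c(1, 2, 3), 2))
  pr <- cluster_factor_profiles(z, rep(1:2, 3))
  expect_equal(pr$tests$H[1], 0)
  expect_equal(pr$tests$p[1], 1)
  expect_error(cluster_factor_profiles(z, c(1, 1, 1, 1, 1, 2)), "size < 2")
  expect_error(cluster_factor_profiles(z, rep(1, 6)), "at least 2")
})

test_that("BH adjustment is monotone and never below raw p", {
  set.seed(3)
  z <- matrix(rnorm(90 * 6), 90, 6)
  pr <- cluster_factor_profiles(z, rep(1:3, each = 30))
  expect_true(all(pr$tests$p_adj >= pr$tests$p - 1e-15))
  o <- order(pr$tests$p)
  expect_true(all(diff(pr$tests$p_adj[o]) >= -1e-15))
})

test_that("centroid distances follow Euclidean geometry", {
  z <- rbind(matrix(0, 10, 3),
             matrix(rep(c(3, 4, 0), each = 10), 10, 3))
  d <- centroid_distances(z, rep(1:2, each = 10))
  expect_equal(unname(d), c(0, 5))

  ## invariance under orthogonal rotation
  set.seed(4)
  zz <- matrix(rnorm(60 * 4), 60, 4)
  lab <- rep(1:3, each = 20)
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(centroid_distances(zz, lab), centroid_distances(zz %*% q, lab),
               tolerance = 1e-10)
})

test_that("planted centroid norms are recovered from sampled clusters", {
  norms <- c(0.9, 2.5, 2.8, 1.5, 1.2)
  set.seed(5)
  dirs <- matrix(rnorm(5 * 8), 5, 8)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cent <- dirs * norms
  cent <- sweep(cent, 2, colMeans(cent))   # center so the cohort mean is 0
  expected <- sqrt(rowSums(cent^2))
  lab <- rep(1:5, each = 200)
  z <- cent[lab, ] + matrix(rnorm(1000 * 8), 1000, 8)
  got <- centroid_distances(z, lab)
  expect_true(all(abs(got - expected) < 0.15))
})

test_that("Cliff's delta matches brute force exactly and is antisymmetric", {
  expect_equal(cliffs_delta(c(1, 2), c(0, 3)), 0)
  expect_equal(cliffs_delta(4:6, 1:3), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cliffs_delta(numeric(0), 1:3), "empty")

  set.seed(6)
  for (i in 1:200) {
    nx <- sample(2:30, 1); ny <- sample(2:30, 1)
    x <- sample(-5:5, nx, replace = TRUE)   # plenty of ties
    y <- sample(-5:5, ny, replace = TRUE)
    expect_identical(cliffs_delta(x, y), cliffs_delta_brute(x, y))
    expect_equal(cliffs_delta(x, y), -cliffs_delta(y, x))
  }
})

test_that("SMD uses the pooled SD", {
  expect_equal(smd(c(1, 2, 3), c(1, 2, 3)), 0)
  y <- rnorm(50)
  expect_equal(smd(y + sd(y), y), 1, tolerance = 1e-10)
  ## manual arithmetic on a printed 6-value toy
  expect_equal(smd(c(1, 2, 3), c(2, 4, 6)), -2 / sqrt(2.5), tolerance = 1e-12)
  expect_error(smd(c(1, 1), c(1, 1)), "zero pooled SD")
  expect_error(smd(1, 1:3), "at least 2")
})

test_that("marker ranking surfaces planted markers and ignores feature order", {
  set.seed(7)
  n <- 150
  lab <- rep(1:3, each = 50)
  feats <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(NULL, paste0("f", 1:6)))
  feats[lab == 2, 4] <- feats[lab == 2, 4] + 2
  mt <- marker_ranking(feats, lab)
  top2 <- mt[mt$cluster == 2 & mt$rank == 1, ]
  expect_identical(top2$feature, "f4")
  expect_gt(abs(top2$cliffs_delta), 0.5)

  perm <- sample(6)
  mt_perm <- marker_ranking(feats[, perm], lab)
  for (cl in 1:3) {
    a <- mt[mt$cluster == cl, c("feature", "smd", "cliffs_delta")]
    b <- mt_perm[mt_perm$cluster == cl, c("feature", "smd", "cliffs_delta")]
    expect_equal(a[order(a$feature), ], b[order(b$feature), ],
                 ignore_attr = TRUE)
  }

  const <- cbind(flat = rep(1, n), feats)
  expect_error(mtc <- marker_ranking(const, lab), NA)
  flat_rows <- mtc[mtc$feature == "flat", ]
  expect_true(all(flat_rows$cliffs_delta == 0))
  expect_true(all(flat_rows$rank == max(mtc$rank)))
})

test_that("demographic balance tests behave at the null and under imbalance", {
  set.seed(8)
  ps <- replicate(200, {
    lab <- sample(3, 150, replace = TRUE)
    demographic_balance(lab, runif(150, 20, 90), rbinom(150, 1, 0.6))$age_test$p
  })
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.01); expect_lt(rate, 0.11)

  lab <- rep(1:2, each = 100)
  sex <- c(rep(0, 100), rbinom(100, 1, 0.6))
  b <- demographic_balance(lab, runif(200, 20, 90), sex)
  expect_lt(b$sex_test$p, 1e-3)
  expect_error(demographic_balance(rep(1, 50), runif(50), rbinom(50, 1, 0.5)),
               "at least 2")
})
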