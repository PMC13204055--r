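test_that("noiseless gaussian data recover the SVD loading subspace", {
  set.seed(1)
  n <- 100; d <- 30; k <- 3
  w <- qr.Q(qr(matrix(rnorm(d * k), d, k)))
  z <- matrix(rnorm(n * k), n, k)
  x <- 2 * z %*% t(w)
  fit <- mvfa(x, k = 3, seed = 1, tol = 1e-7)
  ang <- principal_angles_deg(coef(fit), svd(x)$v[, 1:3])
  expect_true(all(ang < 0.01 * 180 / pi))
  expect_equal(variance_explained(fit)$ev_total, 1, tolerance = 1e-6)
})

test_that("ELBO is non-decreasing on mixed-likelihood data with missingness", {
  set.seed(2)
  for (rep in 1:5) {
    n <- 40; k <- 2
    z <- matrix(rnorm(n * k), n, k)
    g <- z %*% matrix(rnorm(2 * 8), 2, 8) + matrix(rnorm(n * 8, sd = 0.7), n, 8)
    p <- plogis(z %*% matrix(rnorm(2 * 6), 2, 6))
    b <- matrix(rbinom(n * 6, 1, p), n, 6)
    g[sample(length(g), 30)] <- NA
    b[sample(length(b), 20)] <- NA
    ds <- multiview_dataset(list(g = g, b = b), c("gaussian", "bernoulli"))
    fit <- mvfa(ds, k = 3, seed = rep, max_iter = 150, tol = 1e-9)
    expect_gte(min(diff(fit$elbo_trace)), -1e-8)
  }
})

test_that("null data prune all factors", {
  x <- matrix(0, 50, 12)
  fit <- mvfa(x, k = 3, seed = 1, max_iter = 100)
  expect_true(all(fit$alpha > 1e3))
  expect_lt(max(abs(fitted(fit))), 1e-3)
})

test_that("ARD prunes surplus factors on low-rank data", {
  set.seed(3)
  n <- 120; d <- 40
  z <- matrix(rnorm(n * 3), n, 3)
  x <- z %*% matrix(rnorm(3 * d), 3, d)
  fit <- mvfa(x, k = 6, seed = 2, tol = 1e-7)
  ev <- variance_explained(fit)$by_factor
  expect_gte(sum(apply(ev, 1, max) < 1e-3), 3L)
})

test_that("variance explained matches an independent reconstruction oracle", {
  cfg <- small_cohort(n = 120, seed = 15, missing_rate = 0.08)
  ch <- generate_cohort(cfg)
  std <- preprocess_views(ch$dataset)
  fit <- mvfa(std, k = 5, seed = 1, max_iter = 300)
  ev <- variance_explained(fit)

  ## oracle: rebuild the scaled data exactly as the model prepares them and
  ## recompute the residual sums directly
  w <- do.call(rbind, fit$w)
  rs <- 0; ss <- 0
  col0 <- 0
  for (m in seq_along(std$views)) {
    xm <- std$views[[m]] / fit$prepared$view_scale[m]
    obs <- !is.na(xm)
    eta <- tcrossprod(fit$z, w[col0 + seq_len(ncol(xm)), , drop = FALSE])
    if (std$likelihoods[[m]] == "bernoulli") {
      eta <- 1 / (1 + exp(-eta))
      cm <- colSums(ifelse(obs, xm, 0)) / colSums(obs)
      ss <- ss + sum((sweep(xm, 2, cm)[obs])^2)
    } else ss <- ss + sum(xm[obs]^2)
    rs <- rs + sum(((xm - eta)[obs])^2)
    col0 <- col0 + ncol(xm)
  }
  expect_equal(ev$ev_total, 1 - rs / ss, tolerance = 1e-10)

  ## zeroed scores explain nothing of a standardized gaussian view
  fit0 <- fit
  fit0$z[] <- 0
  fit0$w <- lapply(fit0$w, function(w) { w[] <- 0; w })
  gds <- multiview_dataset(list(g = std$views$biochemistry), "gaussian")
  fitg <- mvfa(gds, k = 2, seed = 1, max_iter = 50)
  fitg$z[] <- 0
  expect_equal(variance_explained(fitg)$ev_total, 0, tolerance = 1e-12)
})

test_that("model selection prefers the true rank and handles trivial grids", {
  set.seed(6)
  n <- 100; d <- 30
  x <- matrix(rnorm(n * 4), n, 4) %*% matrix(rnorm(4 * d), 4, d)
  sel <- mvfa_select_k(x, k_grid = c(2, 4), seeds = 1, max_iter = 200)
  expect_identical(sel$best_fit$k, 4L)
  one <- mvfa_select_k(x, k_grid = 3, seeds = 1, max_iter = 50)
  expect_identical(one$best_fit$k, 3L)
})

test_that("procrustes stability is invariant to permutation and sign flips", {
  cfg <- small_cohort(n = 150, seed = 16, missing_rate = 0)
  std <- preprocess_views(generate_cohort(cfg)$dataset)
  fit <- mvfa(std, k = 5, seed = 1, max_iter = 200)
  expect_equal(procrustes_stability(fit, fit), 1, tolerance = 1e-12)

  perm <- c(3, 1, 5, 4, 2); signs <- c(1, -1, 1, -1, 1)
  fitp <- fit
  fitp$w <- lapply(fit$w, function(w) sweep(w[, perm], 2, signs, `*`))
  expect_equal(procrustes_stability(fit, fitp), 1, tolerance = 1e-10)

  fit2 <- mvfa(std, k = 5, seed = 99, max_iter = 200)
  expect_gte(procrustes_stability(fit, fit2), 0.95)
  expect_error(procrustes_stability(fit, matrix(0, 3, 5)), "shape")
})

test_that("factor correlation audit counts pairs and flags duplicates", {
  set.seed(7)
  z16 <- matrix(rnorm(50 * 16), 50, 16)
  aud <- factor_correlation_audit(z16)
  expect_identical(aud$n_pairs, 120L)

  zdup <- cbind(z16[, 1], z16[, 1], z16[, 2])
  expect_equal(factor_correlation_audit(zdup)$max_abs, 1)

  zbig <- matrix(rnorm(10000 * 5), 10000, 5)
  expect_lt(factor_correlation_audit(zbig)$max_abs, 0.05)
})

test_that("fits are deterministic and reported scores are centered", {
  cfg <- small_cohort(n = 100, seed = 18)
  std <- preprocess_views(generate_cohort(cfg)$dataset)
  f1 <- mvfa(std, k = 4, seed = 7, max_iter = 120)
  f2 <- mvfa(std, k = 4, seed = 7, max_iter = 120)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  expect_true(all(abs(colMeans(factor_scores(f1))) < 1e-6))
})

test_that("fully observed gaussian fits agree with the PCA subspace", {
  set.seed(11)
  n <- 150; d <- 40; k <- 4
  x <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * d), k, d)
  fit <- mvfa(x, k = k, seed = 3, tol = 1e-7)
  ang <- principal_angles_deg(coef(fit), svd(scale(x, scale = FALSE))$v[, 1:k])
  expect_true(all(ang < 5))
})

test_that("masking pure-noise entries barely moves the loadings", {
  k <- 5
  views <- c(default_manifest(k)[c(1, 10)],
             list(view_spec("noise", 10, "gaussian", integer())))
  cfg <- cohort_config(n_participants = 250, k_true = k, views = views,
                       cluster_centroids = default_centroids(k),
                       missing_rate = 0, seed = 19)
  ch <- generate_cohort(cfg)
  std <- preprocess_views(ch$dataset)
  masked <- std
  set.seed(20)
  nz <- masked$views$noise
  nz[sample(length(nz), length(nz) %/% 2)] <- NA
  masked$views$noise <- nz
  fa <- mvfa(std, k = k, seed = 4, max_iter = 300)
  fb <- mvfa(masked, k = k, seed = 4, max_iter = 300)
  A <- do.call(rbind, fa$w); B <- do.call(rbind, fb$w)
  sv <- svd(crossprod(B, A))
  rmse <- sqrt(mean((A - B %*% (sv$u %*% t(sv$v)))^2))
  expect_lt(rmse, 0.05)
})

test_that("degenerate inputs are rejected with informative errors", {
  x <- matrix(rnorm(40), 10, 4)
  x[1, 1] <- Inf
  expect_error(mvfa(x, k = 2), "non-finite")
  y <- matrix(rnorm(40), 10, 4)
  y[, 2] <- NA
  expect_error(mvfa(y, k = 2), "no observed values")
})

test_that("posterior prediction reproduces training scores on training data", {
  cfg <- small_cohort(n = 80, seed = 22, missing_rate = 0.05)
  std <- preprocess_views(generate_cohort(cfg)$dataset)
  fit <- mvfa(std, k = 4, seed = 5, max_iter = 200)
  pz <- predict(fit, std)
  expect_gt(min(diag(cor(pz, fit$z))), 0.97)
  sim <- simulate(fit, nsim = 1, seed = 1)
  expect_s3_class(sim[[1]], "multiview_dataset")
  expect_identical(dim(sim[[1]]$views[[1]]), dim(std$views[[1]]))
})
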