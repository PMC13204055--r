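test_that("default manifest reproduces the panel structure", {
  man <- default_manifest()
  expect_length(man, 11L)
  nf <- vapply(man, `[[`, integer(1), "n_features")
  lik <- vapply(man, `[[`, character(1), "likelihood")
  expect_true(all(nf >= 5 & nf <= 40))
  expect_identical(sum(nf[lik == "gaussian"]), 97L)
  expect_identical(sum(nf[lik == "bernoulli"]), 21L)
  expect_identical(sum(nf), 118L)
  expect_identical(sort(nf[lik == "bernoulli"]), c(6L, 15L))
})

test_that("generated cohorts are deterministic and respect the config", {
  cfg <- small_cohort(n = 150, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  ## bernoulli views contain only {0, 1, NA}
  for (v in names(a$dataset$views)) {
    if (a$dataset$likelihoods[[v]] == "bernoulli") {
      vals <- a$dataset$views[[v]]
      expect_true(all(vals[!is.na(vals)] %in% c(0, 1)))
    }
  }
  ## loadings vanish outside the active mask
  for (i in seq_along(cfg$views)) {
    vs <- cfg$views[[i]]
    inactive <- setdiff(seq_len(cfg$k_true), vs$active_factors)
    if (length(inactive))
      expect_true(all(a$truth$w_true[[vs$name]][, inactive] == 0))
  }
})

test_that("noiseless single-view rank-1 cohort has rank-1 data", {
  cfg <- cohort_config(
    n_participants = 60, k_true = 1L,
    views = list(view_spec("v", 10, "gaussian", 1L)),
    cluster_centroids = matrix(0, 1, 1), cluster_proportions = 1,
    confound_effects = list(beta_age = 0, beta_age2 = 0, beta_sex = 0),
    noise_sd_gaussian = 0, missing_rate = 0, seed = 2)
  x <- generate_cohort(cfg)$dataset$views$v
  sv <- svd(x)$d
  expect_lt(sv[2] / sv[1], 1e-8)
})

test_that("planted clusters are recoverable from true scores", {
  cfg <- cohort_config(
    n_participants = 400, k_true = 8L,
    cluster_centroids = default_centroids(8L, separation = 8),
    confound_effects = list(beta_age = 0, beta_age2 = 0, beta_sex = 0),
    seed = 21)
  ch <- generate_cohort(cfg)
  km <- stats::kmeans(ch$truth$z_true, centers = 5, nstart = 25)
  expect_gte(adjusted_rand_index(km$cluster, ch$truth$labels_true), 0.99)
})

test_that("no accidental confounding and proportions are respected", {
  cfg <- cohort_config(
    n_participants = 2000,
    confound_effects = list(beta_age = 0, beta_age2 = 0, beta_sex = 0),
    seed = 31)
  ch <- generate_cohort(cfg)
  r <- abs(cor(ch$truth$z_true, ch$truth$age))
  expect_true(all(r < 0.1))
  emp <- tabulate(ch$truth$labels_true, 5) / 2000
  expect_true(all(abs(emp - cfg$cluster_proportions) < 0.03))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_participants = 3,
                             cluster_centroids = default_centroids(8)),
               "more clusters")
  expect_error(cohort_config(cluster_centroids = matrix(0, 5, 3)),
               "columns")
  expect_error(cohort_config(cluster_proportions = rep(0.25, 5)), "sum to 1")
  expect_error(cohort_config(missing_rate = 1), "\\[0, 1\\)")
})

test_that("missingness injection hits the requested rate and is seeded", {
  cfg <- cohort_config(n_participants = 1000, k_true = 5,
                       views = list(view_spec("v", 10, "gaussian", 1:5)),
                       cluster_centroids = default_centroids(5),
                       missing_rate = 0, seed = 3)
  ds <- generate_cohort(cfg)$dataset
  expect_identical(inject_missingness(ds, 0, seed = 1)$views, ds$views)
  m1 <- inject_missingness(ds, 0.1, seed = 7)
  expect_true(mean(is.na(m1$views$v)) >= 0.08 && mean(is.na(m1$views$v)) <= 0.12)
  m2 <- inject_missingness(ds, 0.5, seed = 7)
  m3 <- inject_missingness(ds, 0.5, seed = 7)
  expect_identical(is.na(m2$views$v), is.na(m3$views$v))
  expect_error(inject_missingness(ds, 1), "\\[0, 1\\)")
})

test_that("cohorts round-trip through CSV files", {
  cfg <- small_cohort(n = 40, seed = 13)
  ch <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(ch$dataset, dir, truth = ch$truth)
  back <- read_cohort(dir)
  expect_equal(back$views, ch$dataset$views, tolerance = 1e-12)
  expect_identical(back$likelihoods, ch$dataset$likelihoods)
})
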