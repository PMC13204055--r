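## Synthetic multi-view cohort generator with known ground truth.
##
## The generator plants (i) a low-rank latent factor structure shared across
## views, (ii) demographic confounding of selected factors by age, age^2 and
## sex, (iii) a G-cluster structure in confound-adjusted factor space, and
## (iv) entry-level MCAR missingness — the statistical structure the
## downstream analysis assumes, so every stage can be validated against
## planted truth.

#' Declare one data view (modality)
#'
#' A view is a thematic block of variables sharing a likelihood family.
#'
#' @param name View name.
#' @param n_features Number of variables in the view (>= 1).
#' @param likelihood `"gaussian"` or `"bernoulli"`.
#' @param active_factors Integer indices of the latent factors that load on
#'   this view; loadings are exactly zero outside this set, emulating
#'   ARD-pruned factor--view blocks.
#' @return An object of class `"view_spec"`.
#' @export
view_spec <- function(name, n_features, likelihood = c("gaussian", "bernoulli"),
                      active_factors = integer()) {
  likelihood <- match.arg(likelihood)
  n_features <- as.integer(n_features)
  if (n_features < 1L) stop("'n_features' must be >= 1", call. = FALSE)
  active_factors <- sort(unique(as.integer(active_factors)))
  if (length(active_factors) && any(active_factors < 1L))
    stop("'active_factors' must be positive factor indices", call. = FALSE)
  structure(list(name = as.character(name), n_features = n_features,
                 likelihood = likelihood, active_factors = active_factors),
            class = "view_spec")
}

#' Default view manifest
#'
#' Eleven views mirroring a mixed clinical/psychosocial panel: nine Gaussian
#' views totalling 97 continuous features and two Bernoulli views totalling
#' 21 one-hot binary features (15 social + 6 behavioural-risk), with per-view
#' feature counts between 5 and 40. Each view loads on a deterministic
#' 5-factor subset of the `k_true` latent factors so that every factor is
#' active in several views.
#'
#' @param k_true Number of latent factors the views load on.
#' @return A list of [view_spec()] objects.
#' @export
default_manifest <- function(k_true = 8L) {
  k_true <- as.integer(k_true)
  specs <- list(
    c("biochemistry",       28L), c("hematology",      14L),
    c("anthropometry",       8L), c("blood_pressure",   5L),
    c("physical_function",   6L), c("cognitive",        9L),
    c("emotional",           8L), c("sleep",            7L),
    c("lifestyle_diet",     12L), c("social",          15L),
    c("behavioral_risk",     6L))
  likelihoods <- c(rep("gaussian", 9L), "bernoulli", "bernoulli")
  out <- vector("list", 11L)
  for (i in seq_along(specs)) {
    active <- sort(unique(((i - 1L + 0:4) %% k_true) + 1L))
    out[[i]] <- view_spec(specs[[i]][1L], as.integer(specs[[i]][2L]),
                          likelihoods[i], active)
  }
  out
}

#' Default planted cluster centroids
#'
#' A regular 4-simplex of five cluster centroids embedded in the first five
#' factor dimensions, scaled to pairwise separation `separation` (factor-SD
#' units) and centered at the proportion-weighted mean so the planted
#' structure has no net offset in factor space.
#'
#' @param k_true Number of latent factors (>= 5).
#' @param separation Pairwise centroid distance in factor-SD units.
#' @param proportions Cluster mixing proportions used for the centering.
#' @return A 5 x `k_true` centroid matrix.
#' @export
default_centroids <- function(k_true = 8L, separation = 5.5,
                              proportions = c(82, 99, 304, 302, 414) / 1201) {
  if (k_true < 5L)
    stop("default centroids need k_true >= 5; supply 'cluster_centroids'",
         call. = FALSE)
  u <- diag(5) - 1 / 5                      # simplex, pairwise distance sqrt(2)
  m <- cbind(u * separation / sqrt(2), matrix(0, 5L, k_true - 5L))
  sweep(m, 2L, colSums(m * proportions))
}

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the structure of a mixed-modality human aging cohort:
#' 1201 participants, 11 views with 118 features (97 Gaussian + 21
#' Bernoulli), ages uniform on 18--99 with 74% female, 8 latent factors of
#' which the first four are confounded by age, age squared, or sex, five
#' planted clusters in confound-adjusted factor space (minimum pairwise
#' centroid separation 4 factor-SD, mixing proportions echoing the study's
#' cluster shares), and 10% MCAR missingness per view.
#'
#' @param n_participants Cohort size.
#' @param k_true Number of latent factors.
#' @param views List of [view_spec()]; default [default_manifest()].
#' @param cluster_centroids G x `k_true` matrix of cluster means in
#'   confound-adjusted factor space (units: within-cluster factor SD).
#' @param cluster_proportions Mixing proportions (sum to 1).
#' @param age_range Two-element vector of minimum and maximum age in years.
#' @param female_fraction Probability that a participant is female (coded 1).
#' @param confound_effects List with numeric vectors `beta_age` (per year),
#'   `beta_age2` (per year squared) and `beta_sex`, each of length `k_true`;
#'   age is centered at the midpoint of `age_range` before the linear and
#'   quadratic terms are formed.
#' @param noise_sd_gaussian Residual SD of Gaussian view entries.
#' @param loading_scale SD of nonzero loadings.
#' @param missing_rate Per-view MCAR missingness proportion in `[0, 1)`.
#'   A single value is recycled across views.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 1201L,
                          k_true = 8L,
                          views = default_manifest(k_true),
                          cluster_centroids = default_centroids(k_true),
                          cluster_proportions = c(82, 99, 304, 302, 414) / 1201,
                          age_range = c(18, 99),
                          female_fraction = 0.74,
                          confound_effects = list(
                            beta_age  = c(0.02, 0, 0, 0, rep(0, max(0L, k_true - 4L))),
                            beta_age2 = c(0, 4e-4, 0, 0, rep(0, max(0L, k_true - 4L))),
                            beta_sex  = c(0, 0, 0.5, 0.25, rep(0, max(0L, k_true - 4L)))),
                          noise_sd_gaussian = 1,
                          loading_scale = 0.3,
                          missing_rate = 0.10,
                          seed = 1L) {
  n_participants <- as.integer(n_participants)
  k_true <- as.integer(k_true)
  cluster_centroids <- as.matrix(cluster_centroids)
  g <- nrow(cluster_centroids)
  if (ncol(cluster_centroids) != k_true)
    stop(sprintf("'cluster_centroids' must have %d columns (one per factor), got %d",
                 k_true, ncol(cluster_centroids)), call. = FALSE)
  if (g < 1L) stop("need at least one cluster", call. = FALSE)
  if (g > n_participants)
    stop("more clusters than participants", call. = FALSE)
  if (abs(sum(cluster_proportions) - 1) > 1e-12)
    stop("'cluster_proportions' must sum to 1", call. = FALSE)
  if (length(cluster_proportions) != g)
    stop("'cluster_proportions' length must match the number of centroids",
         call. = FALSE)
  missing_rate <- rep_len(missing_rate, length(views))
  if (any(missing_rate < 0 | missing_rate >= 1))
    stop("'missing_rate' must be in [0, 1)", call. = FALSE)
  for (v in views) {
    if (!inherits(v, "view_spec")) stop("'views' must be view_spec objects", call. = FALSE)
    if (length(v$active_factors) && max(v$active_factors) > k_true)
      stop(sprintf("view '%s' references factors beyond k_true", v$name), call. = FALSE)
  }
  ce <- confound_effects
  for (nm in c("beta_age", "beta_age2", "beta_sex"))
    ce[[nm]] <- rep_len(if (is.null(ce[[nm]])) 0 else ce[[nm]], k_true)
  structure(list(n_participants = n_participants, k_true = k_true,
                 views = views, cluster_centroids = cluster_centroids,
                 cluster_proportions = cluster_proportions,
                 age_range = age_range, female_fraction = female_fraction,
                 confound_effects = ce,
                 noise_sd_gaussian = noise_sd_gaussian,
                 loading_scale = loading_scale,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Bundle per-view matrices into a multi-view dataset
#'
#' @param views Named list of numeric matrices with a shared row (participant)
#'   index; `NA` marks missing entries.
#' @param likelihoods Character vector, one `"gaussian"`/`"bernoulli"` entry
#'   per view (recycled).
#' @param participant_ids Optional participant identifiers.
#' @return An object of class `"multiview_dataset"`: list with elements
#'   `views`, `likelihoods`, `participant_ids` and a `manifest` data frame
#'   (columns view, feature, likelihood).
#' @export
multiview_dataset <- function(views, likelihoods, participant_ids = NULL) {
  if (is.null(names(views)) || any(!nzchar(names(views))))
    stop("'views' must be a named list", call. = FALSE)
  n <- unique(vapply(views, nrow, integer(1)))
  if (length(n) != 1L)
    stop("all views must share the participant index (equal row counts)",
         call. = FALSE)
  likelihoods <- rep_len(likelihoods, length(views))
  if (!all(likelihoods %in% c("gaussian", "bernoulli")))
    stop("likelihoods must be 'gaussian' or 'bernoulli'", call. = FALSE)
  if (is.null(participant_ids)) participant_ids <- sprintf("P%04d", seq_len(n))
  for (i in seq_along(views)) {
    x <- as.matrix(views[[i]])
    storage.mode(x) <- "double"
    if (is.null(colnames(x)))
      colnames(x) <- sprintf("%s_f%02d", names(views)[i], seq_len(ncol(x)))
    if (likelihoods[i] == "bernoulli") {
      vals <- x[!is.na(x)]
      if (length(vals) && !all(vals %in% c(0, 1)))
        stop(sprintf("bernoulli view '%s' contains values outside {0, 1, NA}",
                     names(views)[i]), call. = FALSE)
    }
    rownames(x) <- participant_ids
    views[[i]] <- x
  }
  names(likelihoods) <- names(views)
  manifest <- data.frame(
    view = rep(names(views), vapply(views, ncol, integer(1))),
    feature = unlist(lapply(views, colnames), use.names = FALSE),
    likelihood = rep(likelihoods, vapply(views, ncol, integer(1))),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(views = views, likelihoods = likelihoods,
                 participant_ids = participant_ids, manifest = manifest),
            class = "multiview_dataset")
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("Multi-view dataset: %d participants, %d views, %d features\n",
              length(x$participant_ids), length(x$views), nrow(x$manifest)))
  for (v in names(x$views)) {
    m <- x$views[[v]]
    cat(sprintf("  %-20s %3d features  %-9s  %.1f%% missing\n", v, ncol(m),
                x$likelihoods[[v]], 100 * mean(is.na(m))))
  }
  invisible(x)
}

#' Generate a synthetic multi-view cohort
#'
#' Draws ages, sex, and cluster labels; builds true factor scores as cluster
#' centroid plus standard-normal within-cluster noise plus the configured
#' confound terms; generates Gaussian views as `Z W' + noise` and Bernoulli
#' views as `Bernoulli(sigmoid(Z W'))`; finally applies MCAR missingness.
#' Fully reproducible for a fixed config (the seed lives in the config).
#'
#' @param config A [cohort_config()].
#' @return A list with elements `dataset` (a [multiview_dataset()]) and
#'   `truth` (class `"cohort_truth"`: `z_true`, per-view `w_true`,
#'   `labels_true`, `age`, `sex`, per-view `missing_mask`).
#' @examples
#' cfg <- cohort_config(n_participants = 100, seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort$dataset
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  k <- config$k_true
  g <- nrow(config$cluster_centroids)
  with_seed(config$seed, {
    age <- runif(n, config$age_range[1], config$age_range[2])
    sex <- rbinom(n, 1L, config$female_fraction)   # 1 = female
    labels <- sample.int(g, n, replace = TRUE, prob = config$cluster_proportions)
    z <- config$cluster_centroids[labels, , drop = FALSE] +
      matrix(rnorm(n * k), n, k)
    age_c <- age - mean(config$age_range)
    ce <- config$confound_effects
    conf <- outer(age_c, ce$beta_age) + outer(age_c^2, ce$beta_age2) +
      outer(sex, ce$beta_sex)
    z <- z + conf

    views <- list()
    w_true <- list()
    masks <- list()
    lik <- character(length(config$views))
    for (i in seq_along(config$views)) {
      vs <- config$views[[i]]
      w <- matrix(0, vs$n_features, k)
      nact <- length(vs$active_factors)
      if (nact)
        w[, vs$active_factors] <- matrix(
          rnorm(vs$n_features * nact, sd = config$loading_scale),
          vs$n_features, nact)
      eta <- z %*% t(w)
      x <- if (vs$likelihood == "gaussian") {
        eta + matrix(rnorm(n * vs$n_features, sd = config$noise_sd_gaussian),
                     n, vs$n_features)
      } else {
        matrix(rbinom(n * vs$n_features, 1L, sigmoid(eta)), n, vs$n_features)
      }
      colnames(x) <- sprintf("%s_f%02d", vs$name, seq_len(vs$n_features))
      views[[vs$name]] <- x
      w_true[[vs$name]] <- w
      lik[i] <- vs$likelihood
    }
    dataset <- multiview_dataset(views, lik)
    ## MCAR masks, one RNG draw block per view
    for (i in seq_along(dataset$views)) {
      m <- dataset$views[[i]]
      mask <- matrix(runif(length(m)) < config$missing_rate[i],
                     nrow(m), ncol(m))
      m[mask] <- NA_real_
      dataset$views[[i]] <- m
      masks[[names(dataset$views)[i]]] <- mask
    }
    truth <- structure(list(z_true = z, w_true = w_true, labels_true = labels,
                            age = age, sex = sex, missing_mask = masks),
                       class = "cohort_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Apply additional completely-at-random missingness
#'
#' @param dataset A [multiview_dataset()].
#' @param rate_per_view Missingness proportion(s) in `[0, 1)`, recycled
#'   across views.
#' @param seed Integer seed.
#' @return The dataset with entries masked to `NA`; the realized masks are
#'   attached as attribute `"injected_mask"`.
#' @export
inject_missingness <- function(dataset, rate_per_view, seed = 1L) {
  stopifnot(inherits(dataset, "multiview_dataset"))
  rates <- rep_len(rate_per_view, length(dataset$views))
  if (any(rates < 0 | rates >= 1))
    stop("missingness rates must be in [0, 1)", call. = FALSE)
  masks <- list()
  with_seed(seed, {
    for (i in seq_along(dataset$views)) {
      m <- dataset$views[[i]]
      mask <- matrix(runif(length(m)) < rates[i], nrow(m), ncol(m))
      m[mask] <- NA_real_
      dataset$views[[i]] <- m
      masks[[names(dataset$views)[i]]] <- mask
    }
  })
  attr(dataset, "injected_mask") <- masks
  dataset
}

#' Write a multi-view dataset to plain-text files
#'
#' One CSV per view plus `manifest.csv` (view, feature, likelihood). When a
#' ground-truth object is supplied, sidecar CSVs with true scores, labels,
#' and demographics are written as well.
#'
#' @param dataset A [multiview_dataset()].
#' @param dir Output directory (created if absent).
#' @param truth Optional `"cohort_truth"` object.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir, truth = NULL) {
  stopifnot(inherits(dataset, "multiview_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in names(dataset$views)) {
    df <- data.frame(participant_id = dataset$participant_ids,
                     dataset$views[[v]], check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0(v, ".csv")), row.names = FALSE)
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(data.frame(participant_id = dataset$participant_ids,
                                label = truth$labels_true, age = truth$age,
                                sex = truth$sex),
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
    utils::write.csv(data.frame(participant_id = dataset$participant_ids,
                                truth$z_true),
                     file.path(dir, "ground_truth_scores.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a multi-view dataset written by [write_cohort()]
#'
#' @param dir Directory containing per-view CSVs and `manifest.csv`.
#' @return A [multiview_dataset()].
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  vnames <- unique(manifest$view)
  views <- list()
  lik <- character(length(vnames))
  ids <- NULL
  for (i in seq_along(vnames)) {
    df <- utils::read.csv(file.path(dir, paste0(vnames[i], ".csv")),
                          check.names = FALSE)
    ids <- df$participant_id
    views[[vnames[i]]] <- as.matrix(df[, -1L, drop = FALSE])
    lik[i] <- manifest$likelihood[manifest$view == vnames[i]][1L]
  }
  multiview_dataset(views, lik, participant_ids = ids)
}
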