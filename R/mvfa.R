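## Multi-view Bayesian factor analysis by mean-field variational inference.
##
## Model, per view m with features d and participants n:
##   gaussian view:  x_nd | z, w ~ Normal(z_n . w_d, 1 / tau_d)
##   bernoulli view: x_nd | z, w ~ Bernoulli(sigmoid(z_n . w_d))
## Priors: z_nk ~ N(0, 1); w_dk ~ N(0, 1 / alpha_mk) with per-(view, factor)
## ARD precisions alpha_mk ~ Gamma(a0, b0); per-feature noise precisions
## tau_d ~ Gamma(c0, d0) on gaussian views. Bernoulli likelihoods are
## handled with the Jaakkola-Jordan quadratic lower bound with a per-entry
## variational parameter xi. Missing entries contribute nothing to any
## update. Every update is exact coordinate ascent on the evidence lower
## bound, so the ELBO trace is non-decreasing up to floating-point noise.

## ---- internal: flatten data for fitting -----------------------------------

prepare_mv_data <- function(data, scale_views = TRUE, view_scale = NULL) {
  if (is.matrix(data) || is.data.frame(data))
    data <- multiview_dataset(list(view1 = as.matrix(data)), "gaussian")
  if (is.list(data) && !inherits(data, "multiview_dataset")) {
    lik <- attr(data, "likelihoods") %||% rep("gaussian", length(data))
    data <- multiview_dataset(data, lik)
  }
  stopifnot(inherits(data, "multiview_dataset"))
  vnames <- names(data$views)
  for (v in vnames) {
    m <- data$views[[v]]
    if (any(is.infinite(m))) stop(sprintf("non-finite values in view '%s'", v),
                                  call. = FALSE)
    allmiss <- colSums(!is.na(m)) == 0L
    if (any(allmiss))
      stop(sprintf("feature(s) with no observed values: %s",
                   paste(colnames(m)[allmiss], collapse = ", ")), call. = FALSE)
  }
  if (is.null(view_scale)) {
    view_scale <- vapply(vnames, function(v) {
      if (scale_views && data$likelihoods[[v]] == "gaussian")
        stats::sd(data$views[[v]][!is.na(data$views[[v]])]) else 1
    }, numeric(1))
    view_scale[!is.finite(view_scale) | view_scale == 0] <- 1
  }
  X <- do.call(cbind, lapply(seq_along(vnames), function(i)
    data$views[[i]] / view_scale[i]))
  O <- 1 - is.na(X)
  X0 <- X; X0[is.na(X0)] <- 0
  dm <- vapply(data$views, ncol, integer(1))
  vid <- rep(seq_along(vnames), dm)
  isbern <- rep(unname(data$likelihoods) == "bernoulli", dm)
  list(X = X, X0 = X0, O = O, vid = vid, isbern = isbern,
       gidx = which(!isbern), bidx = which(isbern),
       view_names = vnames, dm = dm, view_scale = view_scale,
       likelihoods = unname(data$likelihoods),
       participant_ids = data$participant_ids)
}

## Gamma-Gamma KL divergence, elementwise
kl_gamma <- function(a, b, a0, b0) {
  (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
}

## ---- fitting --------------------------------------------------------------

#' Fit a multi-view Bayesian factor model
#'
#' Variational inference for probabilistic matrix factorization across
#' several data views with Gaussian or Bernoulli likelihoods, automatic
#' relevance determination (ARD) priors on the loadings, per-feature noise
#' precisions, and native handling of missing entries (they simply drop out
#' of every update; nothing is imputed). Factors are returned ordered by
#' decreasing variance explained, each sign-flipped so its largest-magnitude
#' loading is positive.
#'
#' @param data A [multiview_dataset()], a named list of matrices, or a single
#'   numeric matrix (treated as one Gaussian view). Gaussian views should be
#'   column-standardized first (see [preprocess_views()]).
#' @param k Number of latent factors.
#' @param seed Integer seed; perturbs the PCA-based initialization, making
#'   the fit deterministic given `(data, k, seed)`.
#' @param max_iter Iteration cap.
#' @param tol Relative ELBO-change convergence tolerance, evaluated every
#'   `check_every` iterations.
#' @param check_every Convergence check interval (iterations).
#' @param scale_views If `TRUE`, each Gaussian view is divided by the SD of
#'   its pooled observed entries so no view dominates the likelihood.
#' @param ard_prior,noise_prior Length-2 vectors `(shape, rate)` of the Gamma
#'   hyperpriors on the ARD precisions `alpha` and noise precisions `tau`.
#' @param verbose Print ELBO progress.
#' @return An object of class `"mvfa"`; see Details.
#' @details The returned object contains `z` (N x K posterior-mean factor
#'   scores), `w` (per-view loading matrices), `alpha` (per-view, per-factor
#'   ARD precision means), `tau` (per-feature noise precision means,
#'   Gaussian views), `elbo_trace`, `converged`, and the prepared (scaled)
#'   training data needed by [variance_explained()] and the methods.
#' @seealso [variance_explained()], [mvfa_select_k()],
#'   [procrustes_stability()], [factor_correlation_audit()]
#' @export
mvfa <- function(data, k, seed = 1L, max_iter = 2500L, tol = 1e-4,
                 check_every = 5L, scale_views = TRUE,
                 ard_prior = c(1e-3, 1e-3), noise_prior = c(1e-3, 1e-3),
                 verbose = FALSE) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  pd <- prepare_mv_data(data, scale_views = scale_views)
  X0 <- pd$X0; O <- pd$O
  n <- nrow(X0); D <- ncol(X0)
  M <- length(pd$view_names)
  gidx <- pd$gidx; bidx <- pd$bidx
  a0 <- ard_prior[1]; b0 <- ard_prior[2]
  c0 <- noise_prior[1]; d0 <- noise_prior[2]
  diag_idx <- seq(1L, k * k, by = k + 1L)
  nobs_g <- colSums(O[, gidx, drop = FALSE])

  ## --- initialization: PCA on mean-filled columns, seed-perturbed ---------
  Xfill <- X0 + (1 - O) * rep(colSums(X0) / pmax(colSums(O), 1), each = n)
  ctr <- colMeans(Xfill)
  Xc <- sweep(Xfill, 2L, ctr)
  sv <- svd(Xc, nu = min(k, min(n, D)), nv = 0)
  mZ <- matrix(0, n, k)
  kk0 <- min(k, ncol(sv$u))
  mZ[, seq_len(kk0)] <- sv$u[, seq_len(kk0), drop = FALSE] * sqrt(n - 1)
  with_seed(seed, {
    mZ <- mZ + matrix(stats::rnorm(n * k, sd = 0.1), n, k)
  })
  mW <- t(qr.solve(crossprod(mZ) + diag(1e-6, k), t(mZ) %*% Xc))
  SZ <- matrix(rep(as.vector(diag(1e-2, k)), each = n), n, k * k)
  SW <- matrix(rep(as.vector(diag(1e-2, k)), each = D), D, k * k)
  EzzT <- SZ + t(apply(mZ, 1L, tcrossprod))
  if (k == 1L) EzzT <- SZ + mZ^2
  EwwT <- SW + if (k == 1L) mW^2 else t(apply(mW, 1L, tcrossprod))
  Ealpha <- matrix(1, M, k)
  ElogAlpha <- matrix(0, M, k)
  Etau <- rep(1, length(gidx))
  Elogtau <- rep(0, length(gidx))
  lambda <- matrix(0.125, n, length(bidx))
  xi <- matrix(0, n, length(bidx))
  logdetSZ <- rep(k * log(1e-2), n)
  logdetSW <- rep(k * log(1e-2), D)
  a_alpha <- a0 + outer(vapply(seq_len(M), function(m) sum(pd$vid == m),
                               numeric(1)), rep(1, k)) / 2
  c_tau <- c0 + nobs_g / 2

  elbo_trace <- numeric(0)
  converged <- FALSE
  elbo_prev_check <- -Inf

  for (iter in seq_len(max_iter)) {
    ## entry weights and targets
    Wt <- O
    if (length(gidx))
      Wt[, gidx] <- Wt[, gidx, drop = FALSE] *
        rep(Etau, each = n)
    if (length(bidx))
      Wt[, bidx] <- O[, bidx, drop = FALSE] * (2 * lambda)
    Tg <- O * X0
    if (length(gidx))
      Tg[, gidx] <- Tg[, gidx, drop = FALSE] * rep(Etau, each = n)
    if (length(bidx))
      Tg[, bidx] <- O[, bidx, drop = FALSE] *
        (X0[, bidx, drop = FALSE] - 0.5)

    ## ---- update q(W) ----
    SumZZ <- crossprod(Wt, EzzT)            # D x k^2
    Bw <- crossprod(Tg, mZ)                 # D x k
    for (d in seq_len(D)) {
      P <- matrix(SumZZ[d, ], k, k)
      diag(P) <- diag(P) + Ealpha[pd$vid[d], ]
      ch <- chol((P + t(P)) / 2)
      Sd <- chol2inv(ch)
      md <- drop(Sd %*% Bw[d, ])
      mW[d, ] <- md
      SW[d, ] <- Sd
      logdetSW[d] <- -2 * sum(log(diag(ch)))
      EwwT[d, ] <- Sd + tcrossprod(md)
    }

    ## ---- update q(alpha) ----
    Ew2 <- EwwT[, diag_idx, drop = FALSE]   # D x k
    b_alpha <- b0 + 0.5 * rowsum(Ew2, pd$vid)
    Ealpha <- a_alpha / b_alpha
    ElogAlpha <- digamma(a_alpha) - log(b_alpha)

    ## ---- update q(Z) ----
    SumWW <- Wt %*% EwwT                    # n x k^2
    Bz <- Tg %*% mW                         # n x k
    for (i in seq_len(n)) {
      P <- matrix(SumWW[i, ], k, k)
      diag(P) <- diag(P) + 1
      ch <- chol((P + t(P)) / 2)
      Si <- chol2inv(ch)
      mi <- drop(Si %*% Bz[i, ])
      mZ[i, ] <- mi
      SZ[i, ] <- Si
      logdetSZ[i] <- -2 * sum(log(diag(ch)))
      EzzT[i, ] <- Si + tcrossprod(mi)
    }

    ## ---- second moments of the linear predictor ----
    A2 <- EzzT %*% t(EwwT)                  # n x D, E[(z.w)^2]
    Eta <- mZ %*% t(mW)                     # n x D, E[z.w]

    ## ---- update xi (bernoulli bound) ----
    if (length(bidx)) {
      xi <- sqrt(pmax(A2[, bidx, drop = FALSE], 1e-12))
      lambda <- tanh(xi / 2) / (4 * xi)
    }

    ## ---- update q(tau) (gaussian) ----
    if (length(gidx)) {
      Og <- O[, gidx, drop = FALSE]
      resid2 <- colSums(Og * (X0[, gidx, drop = FALSE]^2 -
                                2 * X0[, gidx, drop = FALSE] *
                                Eta[, gidx, drop = FALSE] +
                                A2[, gidx, drop = FALSE]))
      d_tau <- d0 + resid2 / 2
      Etau <- c_tau / d_tau
      Elogtau <- digamma(c_tau) - log(d_tau)
    }

    ## ---- ELBO ----
    ll_g <- if (length(gidx))
      sum(0.5 * nobs_g * (Elogtau - log(2 * pi)) - 0.5 * Etau * resid2) else 0
    ll_b <- if (length(bidx)) {
      Ob <- O[, bidx, drop = FALSE]
      sum(Ob * (log(sigmoid(xi)) - xi / 2 +
                  lambda * (xi^2 - A2[, bidx, drop = FALSE])) +
            Tg[, bidx, drop = FALSE] * Eta[, bidx, drop = FALSE])
    } else 0
    kl_z <- 0.5 * sum(rowSums(EzzT[, diag_idx, drop = FALSE]) - k - logdetSZ)
    kl_w <- sum(-0.5 * logdetSW - k / 2 -
                  0.5 * rowSums(ElogAlpha[pd$vid, , drop = FALSE]) +
                  0.5 * rowSums(Ealpha[pd$vid, , drop = FALSE] * Ew2))
    kl_a <- sum(kl_gamma(a_alpha, b_alpha, a0, b0))
    kl_t <- if (length(gidx)) sum(kl_gamma(c_tau, d_tau, c0, d0)) else 0
    elbo <- ll_g + ll_b - kl_z - kl_w - kl_a - kl_t
    elbo_trace <- c(elbo_trace, elbo)
    if (verbose && iter %% 25L == 0L)
      message(sprintf("iter %4d  ELBO %.4f", iter, elbo))

    if (iter %% check_every == 0L) {
      if (is.finite(elbo_prev_check) &&
          abs(elbo - elbo_prev_check) / abs(elbo) < tol) {
        converged <- TRUE
        break
      }
      elbo_prev_check <- elbo
    }
  }

  ## ---- order factors by variance explained; fix signs --------------------
  ssx <- sum(O * X0^2)
  r2 <- vapply(seq_len(k), function(kk) {
    rec <- tcrossprod(mZ[, kk], mW[, kk])
    1 - sum(O * (X0 - rec)^2) / ssx
  }, numeric(1))
  ord <- order(r2, decreasing = TRUE)
  signs <- vapply(seq_len(k), function(kk) {
    j <- ord[kk]
    s <- sign(mW[which.max(abs(mW[, j])), j])
    if (s == 0) 1 else s
  }, numeric(1))
  mZ <- sweep(mZ[, ord, drop = FALSE], 2L, signs, `*`)
  mW <- sweep(mW[, ord, drop = FALSE], 2L, signs, `*`)
  SZ <- flat_transform(SZ, ord, signs)
  SW <- flat_transform(SW, ord, signs)
  EzzT <- flat_transform(EzzT, ord, signs)
  EwwT <- flat_transform(EwwT, ord, signs)
  Ealpha <- Ealpha[, ord, drop = FALSE]
  ElogAlpha <- ElogAlpha[, ord, drop = FALSE]

  colnames(mZ) <- colnames(mW) <- paste0("Factor", seq_len(k))
  rownames(mZ) <- pd$participant_ids
  rownames(Ealpha) <- pd$view_names
  colnames(Ealpha) <- colnames(mZ)
  w_views <- lapply(seq_len(M), function(m) {
    wm <- mW[pd$vid == m, , drop = FALSE]
    rownames(wm) <- colnames(pd$X)[pd$vid == m]
    wm
  })
  names(w_views) <- pd$view_names
  tau_named <- Etau
  if (length(gidx)) names(tau_named) <- colnames(pd$X)[gidx]

  structure(list(
    z = mZ, w = w_views, alpha = Ealpha, tau = tau_named,
    xi = xi, elbo_trace = elbo_trace, converged = converged,
    n_iter = length(elbo_trace), k = k, seed = seed,
    posterior = list(SZ = SZ, SW = SW, EzzT = EzzT, EwwT = EwwT),
    prepared = pd,
    settings = list(max_iter = max_iter, tol = tol,
                    check_every = check_every, scale_views = scale_views,
                    ard_prior = ard_prior, noise_prior = noise_prior),
    call = match.call()),
    class = "mvfa")
}

#' Centered factor scores from a fitted model
#'
#' Posterior-mean factor scores with the column means removed (the reporting
#' convention: factor scores are mean-centered across the full sample).
#'
#' @param fit An `"mvfa"` object.
#' @param center Subtract column means (default `TRUE`).
#' @return N x K numeric matrix.
#' @export
factor_scores <- function(fit, center = TRUE) {
  stopifnot(inherits(fit, "mvfa"))
  if (center) scale(fit$z, center = TRUE, scale = FALSE)[, , drop = FALSE]
  else fit$z
}

## ---- variance explained ---------------------------------------------------

#' Variance explained per factor and view
#'
#' For each factor `k` and view `m`, computes
#' `1 - SS(X - z_k w_k') / SS(X)` over the observed entries of the
#' (scaled) view; per-view totals and the overall `ev_total` use the full
#' K-factor reconstruction, aggregated across views weighted by the number
#' of observed entries. Per-cell values are clipped to `[-0.05, 1]` for
#' reporting.
#'
#' @param fit An `"mvfa"` object.
#' @param dataset Optional [multiview_dataset()]; defaults to the training
#'   data stored in the fit (same view scaling is applied).
#' @return A list of class `"mvfa_ev"`: `by_factor` (K x M matrix),
#'   `by_view` (per-view totals), `ev_total`.
#' @export
variance_explained <- function(fit, dataset = NULL) {
  stopifnot(inherits(fit, "mvfa"))
  pd <- if (is.null(dataset)) fit$prepared
        else prepare_mv_data(dataset, scale_views = fit$settings$scale_views,
                             view_scale = fit$prepared$view_scale)
  if (nrow(pd$X0) != nrow(fit$z) || ncol(pd$X0) != sum(pd$dm))
    stop("fit and dataset dimensions disagree", call. = FALSE)
  mW <- do.call(rbind, fit$w)
  if (ncol(pd$X0) != nrow(mW))
    stop("fit and dataset dimensions disagree", call. = FALSE)
  k <- fit$k
  M <- length(pd$view_names)
  ## total SS per view over observed entries; bernoulli views (raw 0/1
  ## coding) are centered at the observed feature means, gaussian views are
  ## assumed standardized so their uncentered SS is used as-is
  Xc <- pd$X0
  if (length(pd$bidx)) {
    cm <- colSums(pd$O[, pd$bidx, drop = FALSE] *
                    pd$X0[, pd$bidx, drop = FALSE]) /
      pmax(colSums(pd$O[, pd$bidx, drop = FALSE]), 1)
    Xc[, pd$bidx] <- sweep(pd$X0[, pd$bidx, drop = FALSE], 2L, cm)
  }
  ss_view <- vapply(seq_len(M), function(m) {
    idx <- pd$vid == m
    sum(pd$O[, idx, drop = FALSE] * Xc[, idx, drop = FALSE]^2)
  }, numeric(1))
  if (any(ss_view == 0))
    stop("view with zero total sum of squares", call. = FALSE)
  ## reconstruction on the data scale: linear for gaussian, probability for
  ## bernoulli views
  data_scale <- function(rec) {
    if (length(pd$bidx))
      rec[, pd$bidx] <- sigmoid(rec[, pd$bidx, drop = FALSE])
    rec
  }
  by_factor <- matrix(NA_real_, k, M,
                      dimnames = list(colnames(fit$z), pd$view_names))
  for (kk in seq_len(k)) {
    rec <- data_scale(tcrossprod(fit$z[, kk], mW[, kk]))
    res <- pd$O * (pd$X0 - rec)^2
    for (m in seq_len(M)) {
      idx <- pd$vid == m
      by_factor[kk, m] <- 1 - sum(res[, idx, drop = FALSE]) / ss_view[m]
    }
  }
  rec_full <- data_scale(tcrossprod(fit$z, mW))
  res_full <- pd$O * (pd$X0 - rec_full)^2
  rs_view <- vapply(seq_len(M), function(m)
    sum(res_full[, pd$vid == m, drop = FALSE]), numeric(1))
  by_view <- 1 - rs_view / ss_view
  names(by_view) <- pd$view_names
  ev_total <- 1 - sum(rs_view) / sum(ss_view)
  structure(list(by_factor = pmin(pmax(by_factor, -0.05), 1),
                 by_view = by_view, ev_total = ev_total),
            class = "mvfa_ev")
}

#' @export
print.mvfa_ev <- function(x, ...) {
  cat(sprintf("Total variance explained (EV_total): %.3f\n", x$ev_total))
  cat("Per-view totals:\n")
  print(round(x$by_view, 3))
  invisible(x)
}

## ---- model selection over K -----------------------------------------------

#' Fit over a grid of factor numbers and select by total variance explained
#'
#' Fits one model per `(k, seed)` combination, records the seed-median
#' `ev_total` per `k` and the mean pairwise Procrustes stability of the
#' loadings across seeds, and returns the single fit with maximal
#' `ev_total`.
#'
#' @param data Input data (as for [mvfa()]).
#' @param k_grid Integer vector of candidate factor numbers.
#' @param seeds Integer vector of initialization seeds per `k`.
#' @param ... Passed to [mvfa()].
#' @return List with `best_fit` (an `"mvfa"`), `table` (per-k summary), and
#'   `fits_ev` (per (k, seed) `ev_total`).
#' @export
mvfa_select_k <- function(data, k_grid, seeds = c(17L, 42L, 2025L), ...) {
  if (!length(k_grid)) stop("'k_grid' must be nonempty", call. = FALSE)
  best <- NULL; best_ev <- -Inf
  rows <- list(); fits_ev <- list()
  for (k in k_grid) {
    fits <- list(); evs <- numeric(length(seeds))
    for (si in seq_along(seeds)) {
      f <- tryCatch(mvfa(data, k = k, seed = seeds[si], ...),
                    error = function(e)
                      stop(sprintf("fit failed at k=%d seed=%d: %s",
                                   k, seeds[si], conditionMessage(e)),
                           call. = FALSE))
      fits[[si]] <- f
      evs[si] <- variance_explained(f)$ev_total
      if (evs[si] > best_ev) { best_ev <- evs[si]; best <- f }
    }
    stab <- NA_real_
    if (length(fits) >= 2L) {
      prs <- combn(length(fits), 2L)
      stab <- mean(apply(prs, 2L, function(ij)
        procrustes_stability(fits[[ij[1]]], fits[[ij[2]]])))
    }
    rows[[as.character(k)]] <- data.frame(
      k = k, ev_total_median = stats::median(evs), ev_total_max = max(evs),
      stability = stab)
    fits_ev[[as.character(k)]] <- evs
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(best_fit = best, table = tab, fits_ev = fits_ev)
}

#' Procrustes stability between two fits
#'
#' Stacks the per-view loadings of each fit into one matrix, finds the
#' orthogonal transform aligning the second to the first (minimizing the
#' Frobenius distance), and returns the mean over factors of the Pearson
#' correlation between matched loading columns. Invariant to factor
#' permutation and sign flips.
#'
#' @param fit_a,fit_b `"mvfa"` objects (or plain loading matrices) with the
#'   same feature space and K.
#' @return Mean aligned correlation in `[-1, 1]`.
#' @export
procrustes_stability <- function(fit_a, fit_b) {
  A <- if (inherits(fit_a, "mvfa")) do.call(rbind, fit_a$w) else as.matrix(fit_a)
  B <- if (inherits(fit_b, "mvfa")) do.call(rbind, fit_b$w) else as.matrix(fit_b)
  if (!all(dim(A) == dim(B)))
    stop("loading matrices have mismatched shapes", call. = FALSE)
  sv <- svd(crossprod(B, A))
  R <- sv$u %*% t(sv$v)
  Bal <- B %*% R
  mean(vapply(seq_len(ncol(A)), function(k) {
    if (stats::sd(A[, k]) == 0 || stats::sd(Bal[, k]) == 0) return(1)
    stats::cor(A[, k], Bal[, k])
  }, numeric(1)))
}

#' Pairwise correlation audit of factor scores
#'
#' All `K (K - 1) / 2` Pearson correlations between factor-score columns,
#' with summary statistics. Near-orthogonality of the factors is an
#' empirical property of the ARD fit, not an imposed constraint; this audit
#' quantifies it.
#'
#' @param fit An `"mvfa"` object or a numeric score matrix with `K >= 2`
#'   columns.
#' @return List: `pairs` (data frame i, j, r), `n_pairs`, `median_abs`,
#'   `p95_abs`, `max_abs`.
#' @export
factor_correlation_audit <- function(fit) {
  z <- if (inherits(fit, "mvfa")) fit$z else as.matrix(fit)
  k <- ncol(z)
  if (k < 2L) stop("need at least 2 factors", call. = FALSE)
  cm <- stats::cor(z)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[upper.tri(cm)]
  list(pairs = data.frame(i = ut[, 1], j = ut[, 2], r = r),
       n_pairs = length(r),
       median_abs = stats::median(abs(r)),
       p95_abs = unname(stats::quantile(abs(r), 0.95)),
       max_abs = max(abs(r)))
}

## ---- S3 methods -----------------------------------------------------------

#' @export
print.mvfa <- function(x, ...) {
  cat(sprintf("Multi-view Bayesian factor model: %d participants, %d views, %d factors\n",
              nrow(x$z), length(x$w), x$k))
  cat(sprintf("ELBO %.2f after %d iterations (%s)\n",
              x$elbo_trace[length(x$elbo_trace)], x$n_iter,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' @export
summary.mvfa <- function(object, ...) {
  ev <- variance_explained(object)
  aud <- if (object$k >= 2L) factor_correlation_audit(object) else NULL
  out <- list(fit = object, ev = ev, audit = aud)
  class(out) <- "summary.mvfa"
  out
}

#' @export
print.summary.mvfa <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nEV_total = %.3f\n", x$ev$ev_total))
  cat("Variance explained per factor (summed over views, observed-entry weighted):\n")
  print(round(sort(rowMeans(x$ev$by_factor), decreasing = TRUE), 3))
  if (!is.null(x$audit))
    cat(sprintf("\nInter-factor |r|: median %.3f, 95th pct %.3f, max %.3f (%d pairs)\n",
                x$audit$median_abs, x$audit$p95_abs, x$audit$max_abs,
                x$audit$n_pairs))
  invisible(x)
}

#' @export
coef.mvfa <- function(object, view = NULL, ...) {
  if (is.null(view)) do.call(rbind, object$w) else object$w[[view]]
}

#' Posterior factor scores for new observations
#'
#' Computes variational posterior means of the factor scores for new rows
#' given the fitted loadings, ARD and noise precisions. Bernoulli views use
#' a few inner sweeps of the quadratic-bound parameter.
#'
#' @param object An `"mvfa"` object.
#' @param newdata A [multiview_dataset()] (or matrix/list) with the same
#'   feature space as the training data.
#' @param inner_iter Inner sweeps for the Bernoulli bound parameters.
#' @param ... Unused.
#' @return N_new x K matrix of posterior-mean scores.
#' @export
predict.mvfa <- function(object, newdata = NULL, inner_iter = 10L, ...) {
  if (is.null(newdata)) return(object$z)
  pd <- prepare_mv_data(newdata, scale_views = object$settings$scale_views,
                        view_scale = object$prepared$view_scale)
  mW <- do.call(rbind, object$w)
  if (ncol(pd$X0) != nrow(mW))
    stop("newdata feature space does not match the fit", call. = FALSE)
  k <- object$k
  n <- nrow(pd$X0)
  EwwT <- object$posterior$EwwT
  bidx <- pd$bidx; gidx <- pd$gidx
  lambda <- matrix(0.125, n, length(bidx))
  mZ <- matrix(0, n, k)
  EzzT <- matrix(rep(as.vector(diag(k)), each = n), n, k * k)
  for (it in seq_len(max(1L, inner_iter))) {
    Wt <- pd$O
    if (length(gidx))
      Wt[, gidx] <- Wt[, gidx, drop = FALSE] * rep(object$tau, each = n)
    if (length(bidx))
      Wt[, bidx] <- pd$O[, bidx, drop = FALSE] * (2 * lambda)
    Tg <- pd$O * pd$X0
    if (length(gidx))
      Tg[, gidx] <- Tg[, gidx, drop = FALSE] * rep(object$tau, each = n)
    if (length(bidx))
      Tg[, bidx] <- pd$O[, bidx, drop = FALSE] *
        (pd$X0[, bidx, drop = FALSE] - 0.5)
    SumWW <- Wt %*% EwwT
    Bz <- Tg %*% mW
    for (i in seq_len(n)) {
      P <- matrix(SumWW[i, ], k, k)
      diag(P) <- diag(P) + 1
      Si <- chol2inv(chol((P + t(P)) / 2))
      mZ[i, ] <- Si %*% Bz[i, ]
      EzzT[i, ] <- Si + tcrossprod(mZ[i, ])
    }
    if (!length(bidx)) break
    A2b <- (EzzT %*% t(EwwT))[, bidx, drop = FALSE]
    xi <- sqrt(pmax(A2b, 1e-12))
    lambda <- tanh(xi / 2) / (4 * xi)
  }
  colnames(mZ) <- colnames(object$z)
  rownames(mZ) <- pd$participant_ids
  mZ
}

#' @export
fitted.mvfa <- function(object, ...) {
  pd <- object$prepared
  eta <- tcrossprod(object$z, do.call(rbind, object$w))
  if (length(pd$bidx))
    eta[, pd$bidx] <- sigmoid(eta[, pd$bidx, drop = FALSE])
  colnames(eta) <- colnames(pd$X)
  rownames(eta) <- pd$participant_ids
  eta
}

#' @export
residuals.mvfa <- function(object, ...) {
  pd <- object$prepared
  r <- pd$X - fitted(object)
  r
}

#' Simulate data from a fitted multi-view factor model
#'
#' Draws new view matrices from the fitted generative model at the posterior
#' means: Gaussian entries from `Normal(z w', 1/tau)`, Bernoulli entries
#' from `Bernoulli(sigmoid(z w'))`, on the training participants.
#'
#' @param object An `"mvfa"` object.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of [multiview_dataset()] objects (length `nsim`).
#' @export
simulate.mvfa <- function(object, nsim = 1, seed = NULL, ...) {
  pd <- object$prepared
  eta <- tcrossprod(object$z, do.call(rbind, object$w))
  n <- nrow(eta)
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      x <- eta
      if (length(pd$gidx))
        x[, pd$gidx] <- eta[, pd$gidx, drop = FALSE] +
          matrix(stats::rnorm(n * length(pd$gidx),
                              sd = rep(1 / sqrt(object$tau), each = n)),
                 n, length(pd$gidx))
      if (length(pd$bidx))
        x[, pd$bidx] <- matrix(
          stats::rbinom(n * length(pd$bidx), 1L,
                        sigmoid(eta[, pd$bidx, drop = FALSE])),
          n, length(pd$bidx))
      ## undo view scaling so simulated data live on the input scale
      views <- lapply(seq_along(pd$view_names), function(m) {
        xm <- x[, pd$vid == m, drop = FALSE] * pd$view_scale[m]
        colnames(xm) <- colnames(pd$X)[pd$vid == m]
        xm
      })
      names(views) <- pd$view_names
      multiview_dataset(views, pd$likelihoods,
                        participant_ids = pd$participant_ids)
    })
  })
}

#' @export
plot.mvfa <- function(x, ...) {
  ev <- variance_explained(x)
  graphics::barplot(t(pmax(ev$by_factor, 0)), beside = FALSE,
                    col = grDevices::hcl.colors(ncol(ev$by_factor), "Spectral"),
                    las = 2, ylab = "variance explained",
                    main = sprintf("EV_total = %.3f", ev$ev_total), ...)
  invisible(x)
}
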