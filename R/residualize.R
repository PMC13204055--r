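## Demographic residualization of factor scores: per factor, ordinary least
## squares on [1, age_c, age_c^2, sex] with age centered before squaring,
## keeping the residuals as demography-adjusted scores.

#' Residualize factor scores on age, age squared, and sex
#'
#' Fits, for each factor, an ordinary least-squares regression of the score
#' on chronological age (centered), its square, and sex, and returns the
#' residuals. By exact OLS algebra the residuals are orthogonal to every
#' design column; the accompanying audit reports Spearman correlation with
#' age and Cohen's d by sex before and after adjustment.
#'
#' @param z N x K matrix of factor scores (e.g. [factor_scores()]).
#' @param age Numeric vector of ages in years (no missing values).
#' @param sex 0/1 vector (coding declared by the caller; coefficient
#'   `beta_sex` refers to the level coded 1).
#' @param center_age Center age at its mean before squaring (default), which
#'   decorrelates the linear and quadratic terms.
#' @return Object of class `"residualized_scores"`: `z_res` (N x K residual
#'   matrix), `coefficients` (4 x K: intercept, beta_age, beta_age2,
#'   beta_sex on the centered-age scale), `audit` (per-factor before/after
#'   statistics).
#' @export
residualize_factors <- function(z, age, sex, center_age = TRUE) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n <= 4L) stop("need more than 4 participants", call. = FALSE)
  if (anyNA(age) || anyNA(sex)) {
    bad <- which(is.na(age) | is.na(sex))
    stop(sprintf("missing covariates for participant(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (length(age) != n || length(sex) != n)
    stop("covariate length must match the score matrix", call. = FALSE)
  age_c <- if (center_age) age - mean(age) else age
  X <- cbind(`(Intercept)` = 1, age = age_c, age2 = age_c^2, sex = sex)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear design (is age constant?)", call. = FALSE)
  fit <- qr.coef(qrX, z)
  res <- z - X %*% fit
  dimnames(res) <- dimnames(z)
  audit <- data.frame(
    factor = colnames(z) %||% paste0("Factor", seq_len(ncol(z))),
    spearman_age_before = apply(z, 2L, function(v)
      stats::cor(v, age, method = "spearman")),
    spearman_age_after = apply(res, 2L, function(v)
      stats::cor(v, age, method = "spearman")),
    cohens_d_sex_before = apply(z, 2L, cohens_d, g = sex),
    cohens_d_sex_after = apply(res, 2L, cohens_d, g = sex),
    row.names = NULL)
  structure(list(z_res = res, coefficients = fit, audit = audit,
                 age = age, sex = sex, center_age = center_age),
            class = "residualized_scores")
}

cohens_d <- function(v, g) {
  x <- v[g == 1]; y <- v[g == 0]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sex group needs at least 2 members", call. = FALSE)
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' @export
print.residualized_scores <- function(x, ...) {
  cat(sprintf("Residualized factor scores: %d participants x %d factors\n",
              nrow(x$z_res), ncol(x$z_res)))
  cat(sprintf("max |Spearman rho with age|: %.4f (before: %.4f)\n",
              max(abs(x$audit$spearman_age_after)),
              max(abs(x$audit$spearman_age_before))))
  cat(sprintf("max |Cohen's d by sex|:      %.4f (before: %.4f)\n",
              max(abs(x$audit$cohens_d_sex_after)),
              max(abs(x$audit$cohens_d_sex_before))))
  invisible(x)
}

#' @export
residuals.residualized_scores <- function(object, ...) object$z_res

#' Confound-removal audit
#'
#' Per-factor Spearman correlation with age and Cohen's d (pooled SD) by
#' sex, with the maxima over factors — the check that demography no longer
#' structures the adjusted scores.
#'
#' @param z_res N x K matrix of (residualized) scores, or a
#'   `"residualized_scores"` object.
#' @param age,sex Covariates (taken from the object when omitted).
#' @return List: `per_factor` data frame, `max_abs_spearman_age`,
#'   `max_abs_cohens_d_sex`.
#' @export
confound_audit <- function(z_res, age = NULL, sex = NULL) {
  if (inherits(z_res, "residualized_scores")) {
    age <- age %||% z_res$age
    sex <- sex %||% z_res$sex
    z_res <- z_res$z_res
  }
  z_res <- as.matrix(z_res)
  if (length(age) != nrow(z_res) || length(sex) != nrow(z_res))
    stop("covariate length must match the score matrix", call. = FALSE)
  rho <- apply(z_res, 2L, function(v) stats::cor(v, age, method = "spearman"))
  d <- apply(z_res, 2L, cohens_d, g = sex)
  list(per_factor = data.frame(
         factor = colnames(z_res) %||% paste0("Factor", seq_len(ncol(z_res))),
         spearman_age = rho, cohens_d_sex = d, row.names = NULL),
       max_abs_spearman_age = max(abs(rho)),
       max_abs_cohens_d_sex = max(abs(d)))
}
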