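## Independent brute-force oracles used to validate the fast implementations.

## Cliff's delta by full pairwise enumeration
cliffs_delta_brute <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  gt <- sum(outer(x, y, `>`))
  lt <- sum(outer(x, y, `<`))
  (gt - lt) / (length(x) * length(y))
}

## ARI from pair-agreement counts (independent of the contingency-table route)
ari_brute <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

## principal angles (degrees) between the column spans of two matrices
principal_angles_deg <- function(a, b) {
  qa <- qr.Q(qr(a)); qb <- qr.Q(qr(b))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

## small mixed-likelihood cohort used across tests
small_cohort <- function(n = 200, seed = 5, k_true = 5,
                         missing_rate = 0.05) {
  cohort_config(n_participants = n, k_true = k_true,
                views = default_manifest(k_true),
                cluster_centroids = default_centroids(k_true),
                missing_rate = missing_rate, seed = seed)
}

## a quicker boosting backend for unit tests (fewer trees)
fast_backend <- function() xgb_backend(nrounds = 60L)
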