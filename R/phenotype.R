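## Phenotype characterization: per-cluster factor Z-profiles with
## Kruskal-Wallis + BH-FDR significance flags, centroid distances from the
## global origin, one-vs-rest marker rankings by effect size (SMD, Cliff's
## delta), and demographic balance tests.

#' Per-cluster factor profiles with significance flags
#'
#' Mean (residualized) factor score per cluster, a tie-corrected
#' Kruskal-Wallis test across clusters per factor with Benjamini-Hochberg
#' adjustment over the family of factors, and flags marking cluster-factor
#' cells whose absolute mean reaches 0.5 SD.
#'
#' @param z_res N x K matrix of residualized factor scores.
#' @param labels Length-N cluster labels; at least 2 clusters, each of
#'   size >= 2.
#' @param flag_threshold Absolute-mean flag threshold (default 0.5).
#' @return Object of class `"phenotype_profile"`: `means` (G x K),
#'   `flags` (G x K logical), `tests` (per-factor H, p, p_adj),
#'   `sizes`, `centroid_distance`.
#' @export
cluster_factor_profiles <- function(z_res, labels, flag_threshold = 0.5) {
  z_res <- as.matrix(z_res)
  labels <- as.vector(labels)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (any(sizes < 2L))
    stop(sprintf("cluster(s) of size < 2: %s",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")),
         call. = FALSE)
  g <- factor(labels)
  means <- rowsum(z_res, g) / as.vector(table(g))
  tests <- do.call(rbind, lapply(seq_len(ncol(z_res)), function(j) {
    kw <- stats::kruskal.test(z_res[, j], g)
    data.frame(factor = colnames(z_res)[j] %||% paste0("Factor", j),
               H = unname(kw$statistic), p = kw$p.value)
  }))
  ## identical groups give H = 0 and p = 1 under the tie-corrected convention
  tests$p[is.nan(tests$p)] <- 1
  tests$H[is.nan(tests$H)] <- 0
  tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  structure(list(means = means, flags = abs(means) >= flag_threshold,
                 tests = tests, sizes = as.vector(sizes),
                 cluster = rownames(means),
                 centroid_distance = sqrt(rowSums(means^2)),
                 flag_threshold = flag_threshold),
            class = "phenotype_profile")
}

#' @export
print.phenotype_profile <- function(x, ...) {
  cat(sprintf("Phenotype profiles: %d clusters x %d factors\n",
              nrow(x$means), ncol(x$means)))
  cat(sprintf("Cluster sizes: %s\n", paste(x$sizes, collapse = ", ")))
  cat(sprintf("Centroid distances from origin: %s\n",
              paste(round(x$centroid_distance, 3), collapse = ", ")))
  cat(sprintf("Factors significant after FDR (p_adj < 0.05): %d of %d\n",
              sum(x$tests$p_adj < 0.05), nrow(x$tests)))
  invisible(x)
}

#' Euclidean distance of each cluster centroid from the global origin
#'
#' In residualized (mean-centered) factor space, distance from the origin
#' measures how far a phenotype sits from the cohort's average profile.
#'
#' @param z_res N x K score matrix.
#' @param labels Length-N cluster labels.
#' @return Named numeric vector of per-cluster distances.
#' @export
centroid_distances <- function(z_res, labels) {
  z_res <- as.matrix(z_res)
  g <- factor(labels)
  means <- rowsum(z_res, g) / as.vector(table(g))
  stats::setNames(sqrt(rowSums(means^2)), rownames(means))
}

#' Cliff's delta effect size
#'
#' `(#{x_i > y_j} - #{x_i < y_j}) / (n_x n_y)`, computed in O(n log n) via
#' midranks (ties count as neither greater nor less); identical to the
#' quadratic pairwise definition.
#'
#' @param x,y Numeric vectors; missing values are dropped.
#' @return Value in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("empty group", call. = FALSE)
  r <- rank(c(x, y))
  ## U = #{x > y} + 0.5 #{x == y} via the Mann-Whitney statistic
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  (2 * u - nx * ny) / (nx * ny)
}

#' Standardized mean difference
#'
#' `(mean(x) - mean(y))` divided by the pooled SD (group-size-weighted
#' variances).
#'
#' @param x,y Numeric vectors with at least 2 non-missing values each.
#' @return SMD value.
#' @export
smd <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  if (sp == 0) stop("zero pooled SD", call. = FALSE)
  (mean(x) - mean(y)) / sp
}

#' Rank cluster-distinguishing markers by effect size
#'
#' Compares every feature cluster-vs-rest (one-vs-rest) by SMD and Cliff's
#' delta and ranks features within each cluster by `|delta|`.
#'
#' @param features N x P numeric matrix of original (pre-model) variables;
#'   missing values allowed.
#' @param labels Length-N cluster labels.
#' @param top_n Markers retained per cluster (default all).
#' @return Data frame (class `"marker_table"`) with columns cluster,
#'   feature, smd, cliffs_delta, rank. Features that are all-missing or
#'   degenerate within a comparison are skipped with a warning.
#' @export
marker_ranking <- function(features, labels, top_n = Inf) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("feature", seq_len(ncol(features)))
  labels <- as.vector(labels)
  out <- list()
  for (cl in sort(unique(labels))) {
    inx <- labels == cl
    rows <- lapply(colnames(features), function(fn) {
      xv <- features[inx, fn]; yv <- features[!inx, fn]
      xv <- xv[!is.na(xv)]; yv <- yv[!is.na(yv)]
      if (length(xv) < 2L || length(yv) < 2L) {
        warning(sprintf("feature '%s' skipped for cluster %s (too few observed values)",
                        fn, cl), call. = FALSE)
        return(NULL)
      }
      s <- tryCatch(smd(xv, yv), error = function(e) NA_real_)
      data.frame(cluster = cl, feature = fn, smd = s,
                 cliffs_delta = cliffs_delta(xv, yv))
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-abs(tab$cliffs_delta), tab$feature), , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    out[[as.character(cl)]] <- utils::head(tab, top_n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Demographic balance of the phenotypes
#'
#' Kruskal-Wallis test for age across clusters and a chi-square test of the
#' sex-by-cluster table, with BH adjustment within this demographic family.
#' When any expected chi-square cell is below 1 the function warns and falls
#' back to Fisher's exact test.
#'
#' @param labels Cluster labels (>= 2 clusters).
#' @param age Numeric age vector.
#' @param sex 0/1 sex vector.
#' @return List: `age_test` (H, p), `sex_test` (statistic, p, method),
#'   `p_adj` (BH-adjusted pair).
#' @export
demographic_balance <- function(labels, age, sex) {
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least 2 clusters", call. = FALSE)
  kw <- stats::kruskal.test(age, g)
  tab <- table(sex, g)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("expected chi-square cell < 1; using Fisher's exact test",
            call. = FALSE)
    ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = 2000)
    sex_test <- list(statistic = NA_real_, p = ft$p.value, method = "fisher")
  } else {
    cs <- suppressWarnings(stats::chisq.test(tab))
    sex_test <- list(statistic = unname(cs$statistic), p = cs$p.value,
                     method = "chisq")
  }
  p_adj <- stats::p.adjust(c(age = kw$p.value, sex = sex_test$p), method = "BH")
  list(age_test = list(H = unname(kw$statistic), p = kw$p.value),
       sex_test = sex_test, p_adj = p_adj)
}
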