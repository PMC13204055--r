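## Bootstrap consensus K-means over residualized factor scores.
##
## For each candidate K: B bootstrap resamples, k-means (k-means++ init) on
## the unique resampled rows, every cohort member (in- and out-of-bag)
## assigned to its nearest centroid; the consensus matrix is the Monti-style
## ratio of co-clustering counts to co-sampling counts. Partition stability
## is summarized by within-cluster compactness, between-cluster separation,
## PAC, and the mean bootstrap ARI against the consensus partition; K is
## selected by sum of ranks over the four metrics.

## k-means++ seeding
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

## k-means with k-means++ init and restarts; returns stats::kmeans result
kmeans_pp <- function(x, k, nstart = 10L, iter.max = 100L, retry = 5L) {
  best <- NULL
  for (s in seq_len(nstart)) {
    km <- NULL
    for (r in seq_len(retry)) {
      km <- tryCatch(
        stats::kmeans(x, centers = kmeanspp_centers(x, k),
                      iter.max = iter.max),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == k) break
      km <- NULL
    }
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best))
    stop("k-means failed to produce a non-degenerate partition", call. = FALSE)
  best
}

#' Bootstrap consensus matrix from K-means replicates
#'
#' Runs `B` bootstrap replicates of K-means at a fixed `k`: each replicate
#' resamples N participants with replacement, clusters the unique resampled
#' rows (k-means++ initialization, seed `base_seed + b`), and assigns every
#' participant — in-bag or out-of-bag — to the nearest centroid, yielding a
#' full-length partition. Consensus entry (i, j) is the number of replicates
#' in which i and j were both in-bag and co-clustered, divided by the number
#' in which both were in-bag.
#'
#' @param z_res N x K numeric matrix of (residualized) scores, no missing
#'   entries.
#' @param k Number of clusters (`2 <= k <= N`).
#' @param B Number of bootstrap replicates.
#' @param base_seed Base seed; replicate `b` uses `base_seed + b`.
#' @param nstart k-means++ restarts per replicate.
#' @return Object of class `"consensus_matrix"`: `consensus` (N x N),
#'   `co_sample_counts`, `co_cluster_counts`, `replicate_partitions`
#'   (N x B integer matrix), `k`.
#' @export
bootstrap_kmeans <- function(z_res, k, B = 300L, base_seed = 2025L,
                             nstart = 10L) {
  z_res <- as.matrix(z_res)
  if (anyNA(z_res)) stop("scores must not contain missing values", call. = FALSE)
  n <- nrow(z_res)
  if (k > n) stop("more clusters than observations", call. = FALSE)
  if (B < 1L) stop("'B' must be >= 1", call. = FALSE)
  co_clust <- matrix(0, n, n)
  co_samp <- matrix(0, n, n)
  parts <- matrix(NA_integer_, n, B)
  for (b in seq_len(B)) {
    with_seed(base_seed + b, {
      boot <- sample.int(n, n, replace = TRUE)
      rows <- sort(unique(boot))
      km <- kmeans_pp(z_res[rows, , drop = FALSE], k, nstart = nstart)
      ## assign everyone to the nearest centroid
      d <- outer(rowSums(z_res^2), rowSums(km$centers^2), `+`) -
        2 * tcrossprod(z_res, km$centers)
      lab <- max.col(-d, ties.method = "first")
      parts[, b] <- lab
      inbag <- as.numeric(seq_len(n) %in% rows)
      co_samp <- co_samp + tcrossprod(inbag)
      ind <- matrix(0, n, k)
      ind[cbind(seq_len(n), lab)] <- inbag
      co_clust <- co_clust + tcrossprod(ind)
    })
  }
  cons <- ifelse(co_samp > 0, co_clust / pmax(co_samp, 1), 0)
  diag(cons) <- 1
  structure(list(consensus = cons, co_sample_counts = co_samp,
                 co_cluster_counts = co_clust,
                 replicate_partitions = parts, k = k),
            class = "consensus_matrix")
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of strictly-upper-triangle consensus entries falling strictly
#' between `u1` and `u2`; lower values indicate a cleaner, more stable
#' partition.
#'
#' @param consensus N x N consensus matrix (or `"consensus_matrix"` object).
#' @param u1,u2 Ambiguity thresholds, `0 < u1 < u2 < 1`.
#' @return PAC in `[0, 1]`.
#' @export
pac <- function(consensus, u1 = 0.1, u2 = 0.9) {
  if (inherits(consensus, "consensus_matrix")) consensus <- consensus$consensus
  if (u1 >= u2) stop("'u1' must be smaller than 'u2'", call. = FALSE)
  v <- consensus[upper.tri(consensus)]
  mean(v > u1 & v < u2)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table under the
#' permutation model: 1 for identical partitions (up to relabeling), about 0
#' for independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return ARI value (<= 1).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Within-cluster compactness and between-cluster separation
#'
#' Mean consensus over same-cluster pairs (compactness; higher is better)
#' and over different-cluster pairs (separation; lower is better).
#'
#' @param consensus N x N consensus matrix (or `"consensus_matrix"`).
#' @param labels Length-N cluster labels.
#' @return Named vector `c(compactness, separation)`.
#' @export
within_between <- function(consensus, labels) {
  if (inherits(consensus, "consensus_matrix")) consensus <- consensus$consensus
  n <- nrow(consensus)
  if (length(labels) != n) stop("labels must cover all rows", call. = FALSE)
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(consensus)
  within_pairs <- same & ut
  if (!any(within_pairs))
    stop("all-singleton labeling: compactness undefined", call. = FALSE)
  between_pairs <- (!same) & ut
  c(compactness = mean(consensus[within_pairs]),
    separation = if (any(between_pairs)) mean(consensus[between_pairs]) else 0)
}

#' Mean bootstrap ARI against a reference partition
#'
#' @param replicate_partitions N x B matrix of replicate labels (or a
#'   `"consensus_matrix"` object).
#' @param reference_labels Length-N reference partition (typically the
#'   consensus partition at the same K).
#' @return Mean ARI over replicates.
#' @export
ari_bootstrap <- function(replicate_partitions, reference_labels) {
  if (inherits(replicate_partitions, "consensus_matrix"))
    replicate_partitions <- replicate_partitions$replicate_partitions
  replicate_partitions <- as.matrix(replicate_partitions)
  if (ncol(replicate_partitions) < 1L)
    stop("no replicate partitions", call. = FALSE)
  mean(apply(replicate_partitions, 2L, adjusted_rand_index,
             labels_b = reference_labels))
}

#' Final partition by hierarchical aggregation of the consensus matrix
#'
#' Agglomerative clustering (average linkage by default) on the
#' dissimilarity `1 - consensus`, cut at `k` groups.
#'
#' @param consensus N x N consensus matrix (or `"consensus_matrix"`).
#' @param k Number of groups (`>= 2`).
#' @param linkage Linkage method for [stats::hclust()].
#' @return Integer label vector of length N.
#' @export
consensus_partition <- function(consensus, k, linkage = "average") {
  if (inherits(consensus, "consensus_matrix")) consensus <- consensus$consensus
  if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
  if (k > nrow(consensus)) stop("more groups than observations", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = linkage)
  unname(stats::cutree(hc, k = k))
}

#' Rank-based selection of the number of clusters
#'
#' Ranks each K by the four stability metrics in their favorable direction
#' (compactness high, separation low, PAC low, bootstrap ARI high; ties get
#' average ranks) and selects the K with the smallest rank sum, breaking
#' ties toward smaller K.
#'
#' @param metric_table Data frame with columns `k`, `compactness`,
#'   `separation`, `pac`, `ari_bootstrap` (one row per candidate K).
#' @return The table augmented with per-metric ranks and `rank_sum`, plus
#'   attribute `"selected_k"`; also returned in `$selected_k` of
#'   [consensus_cluster()].
#' @export
select_k_consensus <- function(metric_table) {
  need <- c("k", "compactness", "separation", "pac", "ari_bootstrap")
  miss <- setdiff(need, names(metric_table))
  if (length(miss))
    stop(sprintf("missing metric column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (anyNA(metric_table[need]))
    stop("metric table contains missing values", call. = FALSE)
  tab <- metric_table
  tab$rank_compactness <- rank(-tab$compactness, ties.method = "average")
  tab$rank_separation <- rank(tab$separation, ties.method = "average")
  tab$rank_pac <- rank(tab$pac, ties.method = "average")
  tab$rank_ari <- rank(-tab$ari_bootstrap, ties.method = "average")
  tab$rank_sum <- tab$rank_compactness + tab$rank_separation +
    tab$rank_pac + tab$rank_ari
  best <- tab$k[order(tab$rank_sum, tab$k)][1L]
  attr(tab, "selected_k") <- best
  tab
}

#' Bootstrap consensus clustering with stability-based model selection
#'
#' The full consensus stage: for each K in `k_grid`, builds the bootstrap
#' consensus matrix ([bootstrap_kmeans()]), derives the consensus partition
#' by hierarchical aggregation, computes the four stability metrics, and
#' selects K by sum of ranks.
#'
#' @param z_res N x K score matrix (no missing entries).
#' @param k_grid Candidate cluster numbers (default 4:9).
#' @param B Bootstrap replicates per K (default 300).
#' @param pac_thresholds Length-2 vector `(u1, u2)` for PAC (default
#'   `c(0.1, 0.9)`).
#' @param base_seed Base seed for the bootstrap replicates.
#' @param linkage Linkage for consensus aggregation.
#' @param nstart k-means++ restarts per replicate.
#' @return Object of class `"consensus_fit"`: `metrics` (selection table
#'   with ranks), `selected_k`, `labels` (final partition at the selected
#'   K), `per_k` (named list of `"consensus_matrix"` objects and their
#'   partitions).
#' @export
consensus_cluster <- function(z_res, k_grid = 4:9, B = 300L,
                              pac_thresholds = c(0.1, 0.9),
                              base_seed = 2025L, linkage = "average",
                              nstart = 10L) {
  z_res <- as.matrix(z_res)
  if (any(k_grid < 2L) || any(k_grid >= nrow(z_res)))
    stop("'k_grid' values must be >= 2 and < N", call. = FALSE)
  if (B < 2L) stop("'B' must be >= 2", call. = FALSE)
  per_k <- list()
  rows <- list()
  for (k in k_grid) {
    cm <- bootstrap_kmeans(z_res, k, B = B, base_seed = base_seed,
                           nstart = nstart)
    labs <- consensus_partition(cm, k, linkage = linkage)
    wb <- within_between(cm, labs)
    rows[[as.character(k)]] <- data.frame(
      k = k, compactness = wb[["compactness"]],
      separation = wb[["separation"]],
      pac = pac(cm, pac_thresholds[1], pac_thresholds[2]),
      ari_bootstrap = ari_bootstrap(cm, labs))
    per_k[[as.character(k)]] <- list(consensus = cm, labels = labs)
  }
  tab <- select_k_consensus(do.call(rbind, rows))
  rownames(tab) <- NULL
  sel <- attr(tab, "selected_k")
  structure(list(metrics = tab, selected_k = sel,
                 labels = per_k[[as.character(sel)]]$labels,
                 per_k = per_k, k_grid = k_grid, B = B,
                 pac_thresholds = pac_thresholds, base_seed = base_seed,
                 linkage = linkage),
            class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat(sprintf("Bootstrap consensus K-means (B = %d, K grid %s)\n", x$B,
              paste(x$k_grid, collapse = ", ")))
  print(within(x$metrics, {
    compactness <- round(compactness, 3); separation <- round(separation, 3)
    pac <- round(pac, 3); ari_bootstrap <- round(ari_bootstrap, 3)
  })[, c("k", "compactness", "separation", "pac", "ari_bootstrap", "rank_sum")])
  cat(sprintf("Selected K = %d; cluster sizes: %s\n", x$selected_k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' @export
summary.consensus_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.consensus_fit <- function(x, k = x$selected_k, ...) {
  cm <- x$per_k[[as.character(k)]]$consensus$consensus
  ord <- order(x$per_k[[as.character(k)]]$labels)
  graphics::image(cm[ord, ord], useRaster = TRUE, axes = FALSE,
                  main = sprintf("Consensus matrix, K = %d", k), ...)
  invisible(x)
}
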