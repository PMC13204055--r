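## Preprocessing of raw per-view tables into model-ready matrices:
## z-scoring of continuous columns, one-hot expansion of categoricals,
## reverse-coding of positively-directed scale items, and subjective-age
## gap construction. Missing values are carried through untouched — the
## pipeline never imputes.

#' Z-score the columns of a matrix with missing entries
#'
#' Centers and scales each column to zero mean and unit (sample) SD,
#' computing the statistics on the non-missing entries only. Missing entries
#' remain missing.
#'
#' @param x Numeric matrix (may contain `NA`).
#' @return Matrix of the same shape; attributes `"center"` and `"scale"`
#'   hold the per-column statistics.
#' @export
zscore_columns <- function(x) {
  x <- as.matrix(x)
  nobs <- colSums(!is.na(x))
  if (any(nobs < 2L))
    stop(sprintf("column(s) %s have fewer than 2 observed values",
                 paste(colnames(x)[nobs < 2L], collapse = ", ")), call. = FALSE)
  ctr <- colMeans(x, na.rm = TRUE)
  sdev <- apply(x, 2L, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sdev) | sdev == 0
  if (any(bad))
    stop(sprintf("constant column(s): %s",
                 paste(colnames(x)[bad], collapse = ", ")), call. = FALSE)
  out <- sweep(sweep(x, 2L, ctr), 2L, sdev, `/`)
  attr(out, "center") <- ctr
  attr(out, "scale") <- sdev
  out
}

#' One-hot encode a categorical column
#'
#' Expands a factor/character/numeric-coded categorical into one binary
#' column per level (all levels kept, no reference level dropped). A missing
#' source value yields a fully missing row.
#'
#' @param x Vector of categorical values.
#' @param levels Optional explicit level set (default: observed levels).
#' @param prefix Column-name prefix.
#' @return N x L binary matrix with `NA` rows where `x` is missing.
#' @export
one_hot <- function(x, levels = NULL, prefix = "level") {
  f <- factor(x, levels = levels %||% sort(unique(x[!is.na(x)])))
  lv <- base::levels(f)
  if (length(lv) < 2L)
    stop("one-hot encoding needs at least 2 levels", call. = FALSE)
  out <- matrix(NA_real_, length(x), length(lv),
                dimnames = list(NULL, paste(prefix, lv, sep = "_")))
  obs <- !is.na(f)
  out[obs, ] <- 0
  out[cbind(which(obs), as.integer(f)[obs])] <- 1
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-code a bounded scale item
#'
#' Maps `x` to `scale_min + scale_max - x`, so that higher values uniformly
#' indicate greater severity. Applying the transform twice restores the
#' original values.
#'
#' @param x Numeric values within `[scale_min, scale_max]` (`NA` allowed).
#' @param scale_min,scale_max Scale bounds.
#' @return Recoded vector.
#' @export
reverse_code <- function(x, scale_min, scale_max) {
  obs <- x[!is.na(x)]
  if (length(obs) && (any(obs < scale_min) || any(obs > scale_max)))
    stop("values outside the declared scale bounds", call. = FALSE)
  scale_min + scale_max - x
}

#' Subjective-age gap
#'
#' Difference between self-reported subjective age and chronological age;
#' positive values mean feeling older than one is. Missingness propagates.
#'
#' @param subjective_age,chronological_age Numeric vectors (years).
#' @return `subjective_age - chronological_age`.
#' @export
age_gap <- function(subjective_age, chronological_age) {
  subjective_age - chronological_age
}

#' Variable dictionary
#'
#' Tabular metadata mapping each analyzed variable to its view, type, and
#' coding conventions; drives reverse-coding and one-hot expansion.
#'
#' @param id Unique internal identifiers.
#' @param description Full clinical descriptions.
#' @param view View membership.
#' @param type One of `"continuous"`, `"scale"`, `"categorical"`.
#' @param reverse Logical: reverse-code this (scale) item?
#' @param scale_min,scale_max Scale bounds (`NA` for non-scale items).
#' @return A data frame of class `"variable_dictionary"`.
#' @export
variable_dictionary <- function(id, description = id, view, type,
                                reverse = FALSE, scale_min = NA_real_,
                                scale_max = NA_real_) {
  if (anyDuplicated(id)) stop("variable identifiers must be unique", call. = FALSE)
  type <- match.arg(type, c("continuous", "scale", "categorical"),
                    several.ok = TRUE)
  d <- data.frame(id = id, description = description, view = view,
                  type = rep_len(type, length(id)),
                  reverse = rep_len(reverse, length(id)),
                  scale_min = rep_len(scale_min, length(id)),
                  scale_max = rep_len(scale_max, length(id)),
                  stringsAsFactors = FALSE)
  class(d) <- c("variable_dictionary", "data.frame")
  d
}

#' Standardize a multi-view dataset for model input
#'
#' Z-scores every Gaussian view column-wise (statistics from non-missing
#' entries); Bernoulli views pass through unchanged. Never imputes: the set
#' of missing entries is exactly preserved.
#'
#' @param dataset A [multiview_dataset()].
#' @return A standardized [multiview_dataset()].
#' @export
preprocess_views <- function(dataset) {
  stopifnot(inherits(dataset, "multiview_dataset"))
  for (v in names(dataset$views)) {
    if (dataset$likelihoods[[v]] == "gaussian") {
      z <- zscore_columns(dataset$views[[v]])
      attributes(z)[c("center", "scale")] <- NULL
      dimnames(z) <- dimnames(dataset$views[[v]])
      dataset$views[[v]] <- z
    }
  }
  dataset
}
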