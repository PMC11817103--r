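#' Missing-value-tolerant Euclidean distance between samples
#'
#' Pairwise-complete Euclidean distances rescaled for unequal overlap: for
#' samples `i`, `j` sharing `m` observed features out of `p` total,
#' `d = sqrt(sum(shared diffs^2) * p / m)`, so distances stay comparable
#' across pairs with different overlap. On complete data this is the
#' ordinary Euclidean (L2) metric. Pairs with no shared observed feature are
#' undefined (`NA`, with a warning).
#'
#' @param matrix Expression matrix (features x samples), possibly with `NA`s.
#' @return A symmetric samples x samples matrix with a zero diagonal.
#' @details With missing values the rescaled distance need not satisfy the
#'   triangle inequality.
#' @export
tolerant_euclidean <- function(matrix) {
  if (ncol(matrix) < 1L) {
    stop("at least one sample required")
  }
  p <- nrow(matrix)
  obs <- !is.na(matrix)
  x0 <- matrix
  x0[!obs] <- 0
  storage.mode(obs) <- "double"
  a <- crossprod(x0^2, obs)             # sum over shared k of x_ki^2
  s <- a + t(a) - 2 * crossprod(x0)
  m <- crossprod(obs)
  d <- sqrt(pmax(s, 0) * p / m)
  if (any(m == 0 & upper.tri(m))) {
    warning("sample pair(s) share no observed feature; distance undefined")
  }
  d[m == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(colnames(matrix), colnames(matrix))
  d
}

#' Silhouette widths of samples under a labelling
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` on a precomputed distance
#' matrix, where `a` is the mean distance of sample `i` to its own label
#' group and `b` the smallest mean distance to another group. Samples in
#' singleton groups score 0. The mean silhouette width over samples is the
#' Average Silhouette Width (ASW): values near 1 indicate tight, separated
#' clusters, values near 0 random structure, negative values anti-clustering.
#'
#' @param dist Symmetric distance matrix (e.g. [tolerant_euclidean()]).
#' @param labels Category per sample (batch or biological label).
#' @return A list with `widths` (per-sample silhouette), `asw` (mean) and
#'   `median`.
#' @export
silhouette_scores <- function(dist, labels) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist),
            length(labels) == nrow(dist))
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2L) {
    stop("at least two distinct labels required")
  }
  if (anyNA(dist)) {
    stop("distance matrix contains undefined entries")
  }
  sil <- cluster::silhouette(cl, dmatrix = dist)
  widths <- if (is.matrix(sil)) {
    sil[, "sil_width"]
  } else {
    rep(0, nrow(dist))   # every group a singleton: all widths are 0
  }
  names(widths) <- rownames(dist)
  list(widths = widths, asw = mean(widths), median = stats::median(widths))
}

#' Leave-one-out k-nearest-neighbour misclassification rate
#'
#' Classifies every sample by majority vote of its `k` nearest neighbours
#' under the missing-value-tolerant Euclidean distance, leaving the sample
#' itself out, and reports the percentage misclassified. Leave-one-out
#' removes any split randomness; the seed only breaks distance and vote
#' ties, so repeated calls with the same seed are identical.
#'
#' @param matrix Expression matrix (features x samples).
#' @param labels Category per sample; every class needs at least 2 samples.
#' @param k Number of neighbours (default 5), `k <` number of samples.
#' @param seed Integer seed for tie-breaking.
#' @return Misclassification rate in percent.
#' @export
knn_misclassification <- function(matrix, labels, k = 5L, seed = 1L) {
  n <- ncol(matrix)
  if (k >= n) {
    stop("k must be smaller than the number of samples")
  }
  labels <- as.character(labels)
  if (any(table(labels) < 2L)) {
    stop("every class needs at least 2 samples")
  }
  d <- tolerant_euclidean(matrix)
  if (anyNA(d)) {
    stop("distance matrix contains undefined entries")
  }
  .with_seed(seed, {
    wrong <- 0L
    for (i in seq_len(n)) {
      di <- d[i, -i]
      neigh <- order(di, stats::runif(n - 1L))[seq_len(k)]
      votes <- table(labels[-i][neigh])
      top <- names(votes)[votes == max(votes)]
      pick <- if (length(top) > 1L) sample(top, 1L) else top
      if (pick != labels[i]) wrong <- wrong + 1L
    }
    100 * wrong / n
  })
}

#' Per-feature coefficient of variation
#'
#' `sd / |mean|` over the observed cells of each feature. Features with fewer
#' than two observed values or a zero mean are undefined (`NA`). Batch
#' effects inflate the apparent per-feature variance, so successful
#' adjustment lowers the typical CV.
#'
#' @param matrix Expression matrix (features x samples).
#' @return Named numeric vector, one value per feature.
#' @export
feature_cv <- function(matrix) {
  n_obs <- rowSums(!is.na(matrix))
  mu <- rowMeans(matrix, na.rm = TRUE)
  sdv <- apply(matrix, 1L, stats::sd, na.rm = TRUE)
  cv <- sdv / abs(mu)
  cv[n_obs < 2L | mu == 0] <- NA_real_
  names(cv) <- rownames(matrix)
  cv
}

## evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
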