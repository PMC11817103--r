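#' ComBat-style empirical Bayes batch adjustment, tolerant of missing values
#'
#' Parametric empirical-Bayes location/scale adjustment of a sub-matrix
#' (Johnson et al.'s ComBat model, default mode: no covariates, location and
#' scale). All moments are computed over observed cells only, so the kernel
#' accepts matrices with missing entries as long as every (feature, batch)
#' group holds at least two numerical values -- exactly what the dissection
#' step guarantees. On complete data the result matches the reference
#' parametric ComBat to numerical precision.
#'
#' The model standardizes each feature with an observation-weighted grand
#' mean and pooled variance, estimates per-batch location (`gamma`) and scale
#' (`delta`) parameters per feature, shrinks them towards cross-feature
#' priors (normal for location, inverse-gamma for scale, moment-matched), and
#' removes the shrunken effects. Posterior estimates come from the standard
#' fixed-point iteration.
#'
#' @param sub Numeric matrix (features x samples) with at least two rows.
#' @param batch_labels Integer batch index per column; at least two distinct
#'   batches.
#' @param eb_tol Convergence tolerance of the fixed-point iteration.
#' @param eb_maxit Maximum number of iterations.
#' @return The adjusted matrix; missing cells are exactly the input's missing
#'   cells.
#' @references W.E. Johnson, C. Li, A. Rabinovic (2007) Adjusting batch
#'   effects in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1):118-127.
#' @seealso [limma_adjust()]
#' @export
combat_adjust <- function(sub, batch_labels, eb_tol = 1e-4, eb_maxit = 100L) {
  .check_kernel_input(sub, batch_labels)
  batches <- sort(unique(batch_labels))
  obs <- !is.na(sub)
  n_total <- rowSums(obs)

  grand <- rowSums(sub, na.rm = TRUE) / n_total
  batch_means <- vapply(batches, function(b) {
    rowMeans(sub[, batch_labels == b, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(sub)))
  fitted <- batch_means[, match(batch_labels, batches), drop = FALSE]
  var_pooled <- rowSums((sub - fitted)^2, na.rm = TRUE) / n_total
  zero_var <- var_pooled < .Machine$double.eps
  if (any(zero_var)) {
    warning(sum(zero_var), " feature(s) with zero pooled variance; ",
            "variance floored at machine epsilon")
    var_pooled[zero_var] <- .Machine$double.eps
  }
  Z <- (sub - grand) / sqrt(var_pooled)

  out_Z <- Z
  for (b in batches) {
    cols <- batch_labels == b
    Zb <- Z[, cols, drop = FALSE]
    nb <- rowSums(!is.na(Zb))
    if (any(nb < 2L)) {
      stop("every (feature, batch) group needs at least 2 observed values; ",
           "violated for ", sum(nb < 2L), " feature(s) in batch ", b)
    }
    gamma_hat <- rowMeans(Zb, na.rm = TRUE)
    delta_hat <- apply(Zb, 1L, stats::var, na.rm = TRUE)
    delta_hat[delta_hat < .Machine$double.eps] <- .Machine$double.eps
    gamma_bar <- mean(gamma_hat)
    t2 <- stats::var(gamma_hat)
    a_prior <- .aprior(delta_hat)
    b_prior <- .bprior(delta_hat)

    g_old <- gamma_hat
    d_old <- delta_hat
    for (it in seq_len(eb_maxit)) {
      g_new <- (t2 * nb * gamma_hat + d_old * gamma_bar) / (t2 * nb + d_old)
      sum2 <- rowSums((Zb - g_new)^2, na.rm = TRUE)
      d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (is.finite(change) && change < eb_tol) break
    }
    out_Z[, cols] <- (Zb - g_old) / sqrt(d_old)
  }
  out <- out_Z * sqrt(var_pooled) + grand
  dimnames(out) <- dimnames(sub)
  out
}

## moment-matched inverse-gamma hyperparameters for the scale prior
.aprior <- function(d) {
  m <- mean(d)
  s2 <- stats::var(d)
  (2 * s2 + m^2) / s2
}

.bprior <- function(d) {
  m <- mean(d)
  s2 <- stats::var(d)
  (m * s2 + m^3) / s2
}

#' Linear-model batch adjustment, tolerant of missing values
#'
#' Removes additive batch effects per feature by ordinary least squares on
#' the observed cells with an intercept and sum-to-zero batch contrasts (the
#' semantics of limma's `removeBatchEffect` for a single batch factor). With
#' only a batch factor the model is saturated, so the fit reduces to batch
#' means: each observed cell loses its batch mean and regains the unweighted
#' mean of the feature's batch means.
#'
#' @inheritParams combat_adjust
#' @return The adjusted matrix; the missing mask is unchanged.
#' @seealso [combat_adjust()]
#' @export
limma_adjust <- function(sub, batch_labels) {
  .check_kernel_input(sub, batch_labels)
  batches <- sort(unique(batch_labels))
  means <- vapply(batches, function(b) {
    rowMeans(sub[, batch_labels == b, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(sub)))
  if (nrow(sub) == 1L) {
    means <- matrix(means, nrow = 1L)
  }
  # per feature, centre the batch effects over the batches actually observed
  effects <- means
  for (i in seq_len(nrow(sub))) {
    ok <- is.finite(means[i, ])
    effects[i, ok] <- means[i, ok] - mean(means[i, ok])
    effects[i, !ok] <- 0
  }
  out <- sub - effects[, match(batch_labels, batches), drop = FALSE]
  dimnames(out) <- dimnames(sub)
  out
}

.check_kernel_input <- function(sub, batch_labels) {
  stopifnot(is.matrix(sub), is.numeric(sub))
  if (length(batch_labels) != ncol(sub)) {
    stop("batch_labels must have one entry per column")
  }
  if (length(unique(batch_labels)) < 2L) {
    stop("adjustment requires at least two distinct batches")
  }
  if (nrow(sub) < 2L) {
    stop("adjustment requires at least two features; a single-feature ",
         "sub-matrix cannot be adjusted (unique combination)")
  }
  invisible(TRUE)
}
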