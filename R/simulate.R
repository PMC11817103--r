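#' Configuration for the synthetic multi-batch generator
#'
#' Describes a simulated integrated experiment: per-feature baseline levels
#' on a log-intensity-like scale, per-batch additive and multiplicative
#' distortions, a balanced biological grouping nested within batches, and a
#' controllable missingness mechanism. The defaults define a desk-scale
#' dataset (10 batches of 10 samples, 2,000 features, 25% values missing not
#' at random) sized so that a full analysis runs in seconds.
#'
#' @param n_batches Number of batches.
#' @param samples_per_batch Samples per batch.
#' @param n_features Number of features.
#' @param feature_mean_range Range of per-feature means (uniform draw).
#' @param feature_sd_range Range of per-feature standard deviations.
#' @param batch_add_sd Standard deviation of the per-batch additive offset
#'   (normal, mean 0).
#' @param batch_mult_sdlog Log-sd of the per-batch multiplicative factor
#'   (log-normal, log-mean 0). Set to 0 for additive-only effects.
#' @param missing Missingness mechanism: `"mnar"` (probability of dropout is
#'   a decreasing logistic function of the value, emulating low-intensity
#'   censoring), `"mcar"` (uniform dropout) or `"none"`.
#' @param missing_target Target fraction of missing cells, in `[0, 1)`.
#' @param mnar_steepness The logistic scale is the value standard deviation
#'   divided by this; larger values give sharper censoring.
#' @param n_groups Number of biological groups, assigned cyclically within
#'   every batch (so groups are balanced across batches).
#' @param group_effect Additive effect separating consecutive groups on the
#'   affected features.
#' @param affected_fraction Fraction of features carrying the group effect.
#' @param n_unique Number of features to re-mask into unique batch
#'   combinations via [inject_unique()] after generation.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n_batches = 10L, samples_per_batch = 10L,
                       n_features = 2000L,
                       feature_mean_range = c(15, 25),
                       feature_sd_range = c(0.2, 0.5),
                       batch_add_sd = 1, batch_mult_sdlog = 0.15,
                       missing = c("mnar", "mcar", "none"),
                       missing_target = 0.25, mnar_steepness = 3,
                       n_groups = 2L, group_effect = 1,
                       affected_fraction = 0.2,
                       n_unique = 0L, seed = 1L) {
  missing <- match.arg(missing)
  stopifnot(n_batches >= 1, samples_per_batch >= 1, n_features >= 1,
            length(feature_mean_range) == 2L, length(feature_sd_range) == 2L,
            all(feature_sd_range > 0), batch_add_sd >= 0, batch_mult_sdlog >= 0,
            missing_target >= 0, missing_target < 1, mnar_steepness > 0,
            n_groups >= 1, affected_fraction >= 0, affected_fraction <= 1,
            n_unique >= 0)
  structure(list(n_batches = as.integer(n_batches),
                 samples_per_batch = as.integer(samples_per_batch),
                 n_features = as.integer(n_features),
                 feature_mean_range = feature_mean_range,
                 feature_sd_range = feature_sd_range,
                 batch_add_sd = batch_add_sd,
                 batch_mult_sdlog = batch_mult_sdlog,
                 missing = missing, missing_target = missing_target,
                 mnar_steepness = mnar_steepness,
                 n_groups = as.integer(n_groups), group_effect = group_effect,
                 affected_fraction = affected_fraction,
                 n_unique = as.integer(n_unique), seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic multi-batch expression dataset
#'
#' Each value is drawn as `mult_b * N(mu_f, sd_f) + add_b` for feature `f` in
#' batch `b`, plus an additive group effect on the affected features. Under
#' MNAR, dropout probability follows a decreasing logistic in the value whose
#' intercept is calibrated (by root finding on the realized values) so the
#' expected missing fraction equals the target.
#'
#' @param config A `"sim_config"`.
#' @return A list with
#'   \describe{
#'     \item{matrix}{features x samples matrix with `NA` for missing,}
#'     \item{design}{data frame `ID`, `sample`, `batch`,}
#'     \item{truth}{ground truth: batch offsets `add` and factors `mult`,
#'       `feature_mean`, `feature_sd`, per-sample `group`,
#'       `affected_features`, the pre-masking `complete` matrix, the
#'       `missing_mask`, and (when `n_unique > 0`) the injection record.}
#'   }
#' @examples
#' d <- generate_dataset(sim_config(n_batches = 3, samples_per_batch = 4,
#'                                  n_features = 50, seed = 7))
#' dim(d$matrix)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .generate_impl(config))
}

.generate_impl <- function(cf) {
  G <- cf$n_features
  nb <- cf$n_batches
  spb <- cf$samples_per_batch
  N <- nb * spb
  batch <- rep(seq_len(nb), each = spb)
  mu <- stats::runif(G, cf$feature_mean_range[1L], cf$feature_mean_range[2L])
  sg <- stats::runif(G, cf$feature_sd_range[1L], cf$feature_sd_range[2L])
  add <- stats::rnorm(nb, 0, cf$batch_add_sd)
  mult <- exp(stats::rnorm(nb, 0, cf$batch_mult_sdlog))
  group <- rep(rep(seq_len(cf$n_groups), length.out = spb), nb)
  affected <- sort(sample.int(G, round(G * cf$affected_fraction)))

  X <- matrix(stats::rnorm(G * N, mean = mu, sd = sg), G, N)
  X <- sweep(X, 2L, mult[batch], "*")
  X <- sweep(X, 2L, add[batch], "+")
  if (length(affected) && cf$n_groups > 1L) {
    X[affected, ] <- X[affected, ] +
      matrix((group - 1) * cf$group_effect, length(affected), N, byrow = TRUE)
  }
  dimnames(X) <- list(sprintf("feature_%05d", seq_len(G)),
                      sprintf("sample_%03d", seq_len(N)))

  mask <- matrix(FALSE, G, N)
  if (cf$missing != "none" && cf$missing_target > 0) {
    if (cf$missing == "mcar") {
      mask <- matrix(stats::runif(G * N) < cf$missing_target, G, N)
    } else {
      sc <- stats::sd(X) / cf$mnar_steepness
      root <- stats::uniroot(function(c0) {
        mean(stats::plogis((c0 - X) / sc)) - cf$missing_target
      }, lower = min(X) - 20 * stats::sd(X), upper = max(X) + 20 * stats::sd(X),
      tol = 1e-8, extendInt = "upX")
      mask <- matrix(stats::runif(G * N), G, N) <
        stats::plogis((root$root - X) / sc)
    }
  }
  Xm <- X
  Xm[mask] <- NA_real_

  design <- data.frame(ID = colnames(X), sample = seq_len(N), batch = batch,
                       stringsAsFactors = FALSE)
  truth <- list(add = add, mult = mult, feature_mean = mu, feature_sd = sg,
                group = group, affected_features = rownames(X)[affected],
                complete = X, missing_mask = mask)

  if (cf$n_unique > 0L) {
    inj <- inject_unique(Xm, design, cf$n_unique,
                         seed = sample.int(.Machine$integer.max, 1L))
    Xm <- inj$matrix
    truth$unique_features <- inj$unique_features
    truth$anchor_features <- inj$anchor_features
    truth$crop_targets <- inj$crop_targets
  }
  list(matrix = Xm, design = design, truth = truth)
}

#' Re-mask features into unique batch combinations
#'
#' Engineers `count` features whose combination of sufficient batches has
#' multiplicity 1, for exercising the unique-removal rescue at controlled
#' multiplicity. The construction also guarantees resolvability: a two-batch
#' anchor combination shared by at least two other features is a strict
#' subset of every injected combination, and injected combinations have no
#' subset relation among themselves, so minimal cropping always succeeds.
#'
#' @param matrix Expression matrix.
#' @param design Batch description (data frame or `"batch_design"`).
#' @param count Number of unique features to create; `0` is the identity.
#' @param seed Integer seed (selects which features are re-masked).
#' @return A list with the modified `matrix`, `unique_features`,
#'   `anchor_features`, and `crop_targets` (the anchor combination each
#'   injected feature is expected to be cropped to).
#' @details Injection requires features that are present in every batch and
#'   enough distinct subsets; an error is raised when the construction is
#'   impossible for the given matrix (e.g. too few complete features, or
#'   `count` exceeding the available distinct combinations).
#' @export
inject_unique <- function(matrix, design, count, seed = 1L) {
  count <- as.integer(count)
  stopifnot(count >= 0L, count <= nrow(matrix))
  if (count == 0L) {
    return(list(matrix = matrix, unique_features = character(0),
                anchor_features = character(0), crop_targets = list()))
  }
  .with_seed(seed, .inject_impl(matrix, design, count))
}

.inject_impl <- function(matrix, design, count) {
  batch <- .align_batches(matrix, design)
  n <- max(batch)
  if (n < 4L) {
    stop("unique injection needs at least 4 batches")
  }
  pres <- presence_table(matrix, batch)
  combos <- apply(pres, 1L, feature_combination, simplify = FALSE)
  keys <- vapply(combos, paste, character(1), collapse = ",")
  full_key <- paste(seq_len(n), collapse = ",")
  complete_feats <- which(keys == full_key)
  anchor <- c(1L, 2L)
  anchor_key <- paste(anchor, collapse = ",")
  n_anchors_needed <- max(0L, 2L - sum(keys == anchor_key))
  if (length(complete_feats) < count + n_anchors_needed) {
    stop("impossible construction: only ", length(complete_feats),
         " fully present features for count = ", count)
  }
  chosen <- sample(complete_feats, count + n_anchors_needed)
  anchors <- utils::head(chosen, n_anchors_needed)
  uniques <- utils::tail(chosen, count)

  # distinct removal sets avoiding the anchor batches and, to rule out crop
  # targets other than the anchor, avoiding subset relations among the
  # injected combinations: all removal sets have equal size
  pool <- setdiff(seq_len(n), anchor)
  targets <- list()
  size <- 1L
  while (length(targets) < count) {
    if (size > length(pool)) {
      stop("impossible construction: not enough distinct combinations")
    }
    cand_sets <- utils::combn(pool, size, simplify = FALSE)
    for (s in cand_sets) {
      u <- setdiff(seq_len(n), s)
      key <- paste(u, collapse = ",")
      if (!(key %in% keys) && !any(vapply(targets, function(t0) {
            identical(t0, u)
          }, logical(1)))) {
        targets[[length(targets) + 1L]] <- u
        if (length(targets) == count) break
      }
    }
    size <- size + 1L
  }
  if (length(unique(lengths(targets))) > 1L) {
    stop("impossible construction: injected combinations would nest")
  }

  out <- matrix
  for (a in anchors) {
    out[a, !(batch %in% anchor)] <- NA_real_
  }
  for (i in seq_along(uniques)) {
    out[uniques[i], batch %in% setdiff(seq_len(n), targets[[i]])] <- NA_real_
  }
  ids <- rownames(matrix)
  list(matrix = out,
       unique_features = ids[uniques],
       anchor_features = ids[anchors],
       crop_targets = stats::setNames(rep(list(anchor), count), ids[uniques]))
}
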