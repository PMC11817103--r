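#' Batch (or block) presence table under the sufficiency rule
#'
#' A feature is *present* in a unit (batch, or block of batches) when the unit
#' holds at least `min_count` numerical values for it. The downstream
#' adjustment kernels estimate a location and a scale per (feature, batch)
#' group, which requires at least two observed values; a feature with one or
#' zero values in a batch is treated as absent from that batch.
#'
#' @param matrix Expression matrix (features x samples).
#' @param design A `"batch_design"` (see [canonicalize_design()]) aligned with
#'   the matrix columns, or an integer vector of unit indices per column.
#' @param min_count Minimum number of observed values per unit (default 2).
#' @return A logical matrix, features x units.
#' @export
presence_table <- function(matrix, design, min_count = 2L) {
  if (min_count < 1L) {
    stop("min_count must be >= 1")
  }
  units <- .align_batches(matrix, design)
  n_units <- max(units)
  obs <- !is.na(matrix)
  pres <- vapply(seq_len(n_units), function(u) {
    rowSums(obs[, units == u, drop = FALSE]) >= min_count
  }, logical(nrow(matrix)))
  if (nrow(matrix) == 1L) {
    pres <- matrix(pres, nrow = 1L)
  }
  dimnames(pres) <- list(rownames(matrix), seq_len(n_units))
  pres
}

#' Combination of a presence row
#'
#' The combination of a feature is the index set of units in which it is
#' present, e.g. presence `(TRUE, TRUE, FALSE, TRUE)` gives `{1, 2, 4}`.
#' Combinations with fewer than two batches mark a feature unadjustable.
#'
#' @param presence_row Logical vector over units.
#' @return Sorted integer vector of unit indices.
#' @export
feature_combination <- function(presence_row) {
  which(as.logical(presence_row))
}

#' Upper bound on the number of sub-matrices
#'
#' With `n` units, only combinations of two or more units can be adjusted, so
#' the dissection can produce at most `sum(choose(n, 2:n)) = 2^n - n - 1`
#' distinct sub-matrices, and never more than one per feature:
#' `min(F, 2^n - n - 1)`.
#'
#' @param n Number of units (batches or blocks), `n >= 1`.
#' @param F Number of features, `F >= 0`.
#' @return The bound as a double (it can exceed the integer range).
#' @export
max_submatrix_bound <- function(n, F) {
  stopifnot(n >= 1, F >= 0)
  min(as.double(F), 2^n - n - 1)
}

#' Dissect a matrix into combination-keyed sub-matrices
#'
#' Groups features by their combination of present units and attaches, for
#' each distinct combination, the sample columns of the member batches. A
#' feature is adjustable when its retained columns span at least two *actual*
#' batches; under blocking a combination consisting of a single block still
#' qualifies when that block contains two or more batches, because adjustment
#' always operates at batch granularity. Features with fewer than two spanned
#' batches are reported as unadjustable.
#'
#' @param matrix Expression matrix, canonical column order.
#' @param presence Logical presence table (features x units), batch-level
#'   from [presence_table()] or block-level from [blocked_presence()].
#' @param design A `"batch_design"` aligned with the matrix columns.
#' @param blockmap Optional `"block_map"` when `presence` is at block
#'   granularity; `NULL` for batch granularity.
#' @return An object of class `"dissection_plan"`: list with
#'   \describe{
#'     \item{submatrices}{list of sub-matrices, each holding `combination`
#'       (unit indices), `batches` (actual batch indices covered),
#'       `features` (row indices), `feature_ids`, `columns` (column indices)
#'       and `col_batch` (batch index per retained column),}
#'     \item{unadjustable}{data frame of dropped features with a reason,}
#'     \item{t}{number of sub-matrices,}
#'     \item{t_multi}{number of sub-matrices spanning two or more units,}
#'     \item{t_max}{the [max_submatrix_bound()] for `t_multi`,}
#'     \item{n_units}{number of units.}
#'   }
#' @details Sub-matrices are emitted in order of first appearance of their
#'   combination; within a sub-matrix, features keep the input row order.
#' @export
dissect <- function(matrix, presence, design, blockmap = NULL) {
  batch <- .align_batches(matrix, design)
  n_units <- ncol(presence)
  unit_batches <- if (is.null(blockmap)) {
    as.list(seq_len(n_units))
  } else {
    stopifnot(length(blockmap$blocks) == n_units)
    blockmap$blocks
  }
  stopifnot(nrow(presence) == nrow(matrix))
  keys <- apply(presence, 1L, function(r) paste(which(r), collapse = ","))
  n_span <- vapply(seq_len(nrow(presence)), function(i) {
    length(unlist(unit_batches[which(presence[i, ])]))
  }, integer(1))
  adjustable <- n_span >= 2L
  unadj <- data.frame(feature = rownames(matrix)[!adjustable],
                      reason = ifelse(n_span[!adjustable] == 0L,
                                      "absent from all batches",
                                      "present in fewer than two batches"),
                      stringsAsFactors = FALSE)
  subs <- list()
  for (key in unique(keys[adjustable])) {
    feats <- unname(which(adjustable & keys == key))
    combo <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
    batches <- sort(unlist(unit_batches[combo]))
    columns <- which(batch %in% batches)
    subs[[length(subs) + 1L]] <- list(combination = combo,
                                      batches = batches,
                                      features = feats,
                                      feature_ids = rownames(matrix)[feats],
                                      columns = columns,
                                      col_batch = batch[columns])
  }
  t_multi <- sum(vapply(subs, function(s) length(s$combination) >= 2L, logical(1)))
  structure(list(submatrices = subs,
                 unadjustable = unadj,
                 t = length(subs),
                 t_multi = t_multi,
                 t_max = max_submatrix_bound(n_units, nrow(matrix)),
                 n_units = n_units),
            class = "dissection_plan")
}

#' @export
print.dissection_plan <- function(x, ...) {
  cat("dissection plan:", x$t, "sub-matrices over", x$n_units, "units",
      sprintf("(bound %g)", x$t_max), "\n")
  cat("unadjustable features:", nrow(x$unadjustable), "\n")
  invisible(x)
}

#' Rebuild the full matrix from adjusted sub-matrices
#'
#' Reassembles a matrix with the dimensions and dimnames of `template` from
#' per-sub-matrix adjusted values. Cells outside every sub-matrix (values in
#' insufficient batches, cropped entries) are missing in the output.
#' Features covered by no sub-matrix are dropped unless `keep_unadjusted` is
#' set, in which case they remain as all-missing rows.
#'
#' @param plan A `"dissection_plan"`.
#' @param adjusted List of numeric matrices parallel to `plan$submatrices`,
#'   each with the same dimensions as its sub-matrix.
#' @param template Matrix supplying output dimensions and dimnames.
#' @param keep_unadjusted Keep uncovered features as all-`NA` rows?
#' @return Numeric matrix in the template's row/column order.
#' @export
rebuild <- function(plan, adjusted, template, keep_unadjusted = FALSE) {
  stopifnot(inherits(plan, "dissection_plan"),
            length(adjusted) == length(plan$submatrices))
  out <- matrix(NA_real_, nrow(template), ncol(template),
                dimnames = dimnames(template))
  covered <- matrix(FALSE, nrow(template), ncol(template))
  for (i in seq_along(plan$submatrices)) {
    s <- plan$submatrices[[i]]
    vals <- adjusted[[i]]
    stopifnot(nrow(vals) == length(s$features),
              ncol(vals) == length(s$columns))
    if (any(covered[s$features, s$columns])) {
      stop("sub-matrices overlap: dissection must partition the matrix")
    }
    covered[s$features, s$columns] <- TRUE
    out[s$features, s$columns] <- vals
  }
  if (!keep_unadjusted) {
    keep <- sort(unique(unlist(lapply(plan$submatrices, `[[`, "features"))))
    out <- out[keep, , drop = FALSE]
  }
  out
}
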