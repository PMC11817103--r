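#' Find features with a unique batch combination
#'
#' A feature whose combination of sufficient batches is shared with no other
#' feature ends up alone in its sub-matrix, which the adjustment kernels
#' cannot process; without rescue it would be discarded. Only adjustable
#' combinations (two or more batches) are considered: features with fewer
#' sufficient batches are unadjustable regardless of multiplicity.
#'
#' @param combinations List of integer combinations, one per feature,
#'   at batch granularity.
#' @return Indices (named after the features, when the list is named) of the
#'   features whose combination has multiplicity 1.
#' @seealso [choose_crop()], [apply_unique_removal()]
#' @export
find_unique <- function(combinations) {
  sizes <- lengths(combinations)
  keys <- vapply(combinations, paste, character(1), collapse = ",")
  keys[sizes < 2L] <- NA_character_
  tab <- table(keys[!is.na(keys)])
  idx <- which(!is.na(keys) & tab[keys] == 1L)
  if (!is.null(names(combinations))) {
    names(idx) <- names(combinations)[idx]
  }
  idx
}

#' Choose the minimal crop for a unique combination
#'
#' Selects, among the other features' combinations, a strict subset of the
#' unique combination to crop down to, removing as little information as
#' possible: candidates must span at least two batches, and the one cropping
#' the fewest batches (maximal size) wins. Ties are broken by (1) the most
#' numerical values retained for this feature and then (2) the
#' lexicographically smallest combination, making the choice deterministic.
#'
#' @param unique_combo Integer combination of the unique feature.
#' @param population List of the other features' combinations (the original,
#'   pre-removal multiset).
#' @param value_counts Numeric vector: observed-value count per batch for the
#'   unique feature (indexable by batch number).
#' @return The chosen combination, or `NULL` when no candidate exists.
#' @export
choose_crop <- function(unique_combo, population, value_counts) {
  keys <- unique(vapply(population, paste, character(1), collapse = ","))
  cands <- lapply(strsplit(keys, ",", fixed = TRUE), as.integer)
  cands <- Filter(function(cc) {
    length(cc) >= 2L && length(cc) < length(unique_combo) && all(cc %in% unique_combo)
  }, cands)
  if (!length(cands)) {
    return(NULL)
  }
  sizes <- lengths(cands)
  cands <- cands[sizes == max(sizes)]
  if (length(cands) > 1L) {
    retained <- vapply(cands, function(cc) sum(value_counts[cc]), numeric(1))
    cands <- cands[retained == max(retained)]
  }
  best <- cands[[1L]]
  for (cc in cands[-1L]) {
    if (.lex_less(cc, best)) best <- cc
  }
  best
}

#' Rescue features with unique batch combinations by minimal cropping
#'
#' For every unique feature for which a crop target exists, the values in the
#' cropped-away batches are set missing so that the feature's combination
#' matches at least one other feature, merging it into an existing
#' sub-matrix. Candidate targets are the *non-unique* combinations of the
#' original (pre-removal) multiset -- combinations held by at least two
#' features. Anchoring on a surviving group guarantees the rescue (a unique
#' feature's own combination would vanish when that feature is itself
#' cropped, stranding its dependants in new single-feature sub-matrices) and
#' makes the sub-matrix count decrease by exactly one per resolved feature;
#' because the population is fixed up front, the result does not depend on
#' processing order. Unique features with no valid subset anchor are left
#' untouched and reported; they are dropped downstream.
#'
#' @param matrix Expression matrix in canonical column order.
#' @param combinations List of per-feature batch combinations (see
#'   [presence_table()] and [feature_combination()]).
#' @param design A `"batch_design"` aligned with the matrix columns.
#' @return A list with
#'   \describe{
#'     \item{matrix}{the matrix with cropped cells set to `NA`,}
#'     \item{combinations}{updated combinations,}
#'     \item{crop_records}{data frame with one row per resolved feature:
#'       `feature`, `original`, `cropped`, `batches_removed`,
#'       `values_discarded`,}
#'     \item{unresolved}{ids (or indices) of unique features left unrescued.}
#'   }
#' @export
apply_unique_removal <- function(matrix, combinations, design) {
  batch <- .align_batches(matrix, design)
  stopifnot(length(combinations) == nrow(matrix))
  uniq <- find_unique(combinations)
  records <- list()
  unresolved <- integer(0)
  obs <- !is.na(matrix)
  counts_for <- function(i) {
    vapply(seq_len(max(batch)), function(b) {
      sum(obs[i, batch == b])
    }, numeric(1))
  }
  out <- matrix
  new_combos <- combinations
  anchor_pool <- combinations[setdiff(seq_along(combinations), uniq)]
  for (i in uniq) {
    target <- choose_crop(combinations[[i]], anchor_pool, counts_for(i))
    if (is.null(target)) {
      unresolved <- c(unresolved, i)
      next
    }
    removed <- setdiff(combinations[[i]], target)
    cols <- batch %in% removed
    discarded <- sum(obs[i, cols])
    out[i, cols] <- NA_real_
    new_combos[[i]] <- target
    records[[length(records) + 1L]] <- data.frame(
      feature = if (!is.null(rownames(matrix))) rownames(matrix)[i] else as.character(i),
      original = paste(combinations[[i]], collapse = ","),
      cropped = paste(target, collapse = ","),
      batches_removed = paste(removed, collapse = ","),
      values_discarded = discarded,
      stringsAsFactors = FALSE)
  }
  crop_records <- if (length(records)) {
    do.call(rbind, records)
  } else {
    data.frame(feature = character(0), original = character(0),
               cropped = character(0), batches_removed = character(0),
               values_discarded = numeric(0), stringsAsFactors = FALSE)
  }
  if (!is.null(rownames(matrix)) && length(unresolved)) {
    unresolved <- structure(unresolved, names = rownames(matrix)[unresolved])
  }
  list(matrix = out, combinations = new_combos,
       crop_records = crop_records, unresolved = unresolved)
}
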