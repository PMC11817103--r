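#' Missing-value-tolerant batch effect adjustment
#'
#' Runs the full pipeline on an integrated expression matrix: canonicalize
#' the design, compute batch presence under the sufficiency rule, rescue
#' unique combinations by minimal cropping (optional), order and block
#' batches (optional), dissect the matrix into combination-keyed
#' sub-matrices, adjust every sub-matrix independently with the chosen
#' kernel at actual-batch granularity, and rebuild the matrix in the input's
#' row and column order.
#'
#' Blocking treats groups of neighbouring batches as single units during
#' dissection only; it shrinks the combination space (and with it runtime
#' and the number of sub-matrices) at the price of additional data loss,
#' while adjustment still removes the effect of every real batch. Sorting
#' rearranges batches before blocking to reduce that loss; it has no effect
#' without blocking and is then ignored with a warning.
#'
#' @param matrix Numeric expression matrix (features x samples) with row and
#'   column names, or a path readable by [read_matrix()].
#' @param design Batch description data frame (`ID`, `sample`, `batch`) or a
#'   path readable by [read_description()].
#' @param algorithm `"combat"` (parametric empirical Bayes location/scale,
#'   the default) or `"limma"` (linear-model batch term removal).
#'   Case-insensitive.
#' @param block Block size (number of batches per unit), or `NULL` (default)
#'   for no blocking.
#' @param sort Batch ordering applied before blocking: `"off"` (default),
#'   `"sparsity"`, `"seriation"` or `"jaccard"`.
#' @param ur Rescue features with unique combinations by minimal cropping
#'   (default `TRUE`).
#' @param workers Number of parallel workers for sub-matrix adjustment.
#'   Sub-matrices are independent work items merged deterministically, so
#'   the output is identical for any worker count.
#' @param min_values_per_batch Sufficiency threshold (default 2).
#' @param keep_unadjusted Keep unadjustable features as all-`NA` rows instead
#'   of dropping them.
#' @param verbose Emit progress messages.
#' @return A list of class `"harmonize_result"` with elements `matrix` (the
#'   adjusted matrix, rows = adjusted features in input order, columns in
#'   input order) and `report` (a `"harmonize_report"`; see Details).
#' @details The report records feature accounting (`total`, `considered`,
#'   `dropped` with reasons), sub-matrix counts before and after unique
#'   removal and after blocking, crop records, per-stage timings, and the
#'   configuration. `considered + dropped` always equals `total`.
#' @examples
#' d <- generate_dataset(sim_config(n_batches = 4, samples_per_batch = 5,
#'                                  n_features = 100, seed = 3))
#' res <- harmonize(d$matrix, d$design, algorithm = "limma", verbose = FALSE)
#' res$report
#' @export
harmonize <- function(matrix, design,
                      algorithm = c("combat", "limma"),
                      block = NULL,
                      sort = c("off", "sparsity", "seriation", "jaccard"),
                      ur = TRUE, workers = 1L,
                      min_values_per_batch = 2L,
                      keep_unadjusted = FALSE, verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  say <- function(...) if (verbose) message(...)

  if (is.character(matrix)) matrix <- read_matrix(matrix)
  if (is.character(design)) design <- read_description(design)
  algorithm <- match.arg(tolower(algorithm[1L]), c("combat", "limma"))
  sort <- match.arg(sort)
  workers <- max(1L, as.integer(workers))
  kernel <- if (algorithm == "combat") combat_adjust else limma_adjust

  cd <- canonicalize_design(matrix, design)
  n <- cd$n_batches
  if (n < 2L) {
    stop("at least two batches are required for batch effect adjustment")
  }
  X <- matrix[, cd$perm, drop = FALSE]
  tick("canonicalize")

  pres <- presence_table(X, cd, min_values_per_batch)
  combos <- apply(pres, 1L, feature_combination, simplify = FALSE)
  n_sub_before <- .count_adjustable_combos(combos)
  tick("presence")

  crop_records <- NULL
  unresolved <- integer(0)
  if (ur) {
    urres <- apply_unique_removal(X, combos, cd)
    X <- urres$matrix
    combos <- urres$combinations
    crop_records <- urres$crop_records
    unresolved <- urres$unresolved
    pres <- presence_table(X, cd, min_values_per_batch)
    say("unique removal: ", nrow(crop_records), " feature(s) rescued, ",
        length(unresolved), " unresolved")
  }
  n_sub_after_ur <- .count_adjustable_combos(combos)
  tick("unique_removal")

  blockmap <- NULL
  order_used <- seq_len(n)
  if (!is.null(block)) {
    bo <- if (sort == "off") {
      structure(list(order = seq_len(n), inverse = seq_len(n), method = "off"),
                class = "batch_order")
    } else {
      sort_batches(X, cd, sort, min_values_per_batch)
    }
    order_used <- bo$order
    blockmap <- block_batches(bo, block)
    pres_units <- blocked_presence(pres, blockmap)
    say("blocking: ", length(blockmap$blocks), " block(s) of size <= ", block,
        if (sort != "off") paste0(" after ", sort, " sort") else "")
  } else {
    if (sort != "off") {
      warning("sorting has no effect without blocking; ignored")
    }
    pres_units <- pres
  }
  tick("ordering_blocking")

  plan <- dissect(X, pres_units, cd, blockmap)
  # single-feature sub-matrices cannot be adjusted; drop them with a reason
  singleton <- vapply(plan$submatrices, function(s) length(s$features) == 1L,
                      logical(1))
  if (any(singleton)) {
    ids <- unlist(lapply(plan$submatrices[singleton], `[[`, "feature_ids"))
    plan$unadjustable <- rbind(plan$unadjustable,
                               data.frame(feature = ids,
                                          reason = "unique combination (single-feature sub-matrix)",
                                          stringsAsFactors = FALSE))
    plan$submatrices <- plan$submatrices[!singleton]
    plan$t <- length(plan$submatrices)
    say("dropped ", length(ids), " feature(s) in single-feature sub-matrices")
  }
  if (length(plan$submatrices) == 0L) {
    stop("no adjustable features: all ", nrow(matrix),
         " feature(s) lack two sufficient batches or are unique")
  }
  say("dissection: ", plan$t, " sub-matrix/matrices over ", plan$n_units,
      " unit(s)")
  tick("dissect")

  adjust_one <- function(s) {
    kernel(X[s$features, s$columns, drop = FALSE], s$col_batch)
  }
  adjusted <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(plan$submatrices, adjust_one, mc.cores = workers)
  } else {
    lapply(plan$submatrices, adjust_one)
  }
  errs <- vapply(adjusted, inherits, logical(1), "try-error")
  if (any(errs)) {
    stop("adjustment failed: ", attr(adjusted[[which(errs)[1L]]], "condition")$message)
  }
  tick("adjust")

  out <- rebuild(plan, adjusted, X, keep_unadjusted = keep_unadjusted)
  out <- out[, cd$inv_perm, drop = FALSE]
  tick("rebuild")

  dropped <- plan$unadjustable
  report <- structure(list(
    total_features = nrow(matrix),
    considered = if (keep_unadjusted) nrow(matrix) - nrow(dropped) else nrow(out),
    dropped = dropped,
    n_batches = n,
    n_units = plan$n_units,
    submatrices_before_ur = n_sub_before,
    submatrices_after_ur = n_sub_after_ur,
    submatrices_adjusted = plan$t,
    crop_records = crop_records,
    unresolved_unique = unresolved,
    batch_order = order_used,
    config = list(algorithm = algorithm, block = block, sort = sort, ur = ur,
                  workers = workers,
                  min_values_per_batch = min_values_per_batch,
                  keep_unadjusted = keep_unadjusted),
    timings = timings), class = "harmonize_report")
  say("considered ", report$considered, " / ", report$total_features,
      " feature(s)")
  structure(list(matrix = out, report = report), class = "harmonize_result")
}

## distinct adjustable (>= 2 batches) combination keys
.count_adjustable_combos <- function(combos) {
  keys <- vapply(combos, paste, character(1), collapse = ",")
  length(unique(keys[lengths(combos) >= 2L]))
}

#' @export
print.harmonize_report <- function(x, ...) {
  cat("batch adjustment report\n")
  cat("  algorithm: ", x$config$algorithm,
      if (!is.null(x$config$block)) paste0(", block = ", x$config$block),
      if (x$config$sort != "off") paste0(", sort = ", x$config$sort),
      if (x$config$ur) ", unique removal on" else ", unique removal off",
      "\n", sep = "")
  cat("  batches:", x$n_batches, "| dissection units:", x$n_units, "\n")
  cat("  features considered:", x$considered, "/", x$total_features, "\n")
  cat("  sub-matrices: before unique removal", x$submatrices_before_ur,
      "| after", x$submatrices_after_ur,
      "| adjusted", x$submatrices_adjusted, "\n")
  if (!is.null(x$crop_records)) {
    cat("  rescued unique features:", nrow(x$crop_records),
        "| unresolved:", length(x$unresolved_unique), "\n")
  }
  invisible(x)
}

#' @export
print.harmonize_result <- function(x, ...) {
  cat("adjusted matrix:", nrow(x$matrix), "features x", ncol(x$matrix),
      "samples\n")
  print(x$report)
  invisible(x)
}
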