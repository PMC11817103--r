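#' Jaccard similarity of two index sets
#'
#' `|a ∩ b| / |a ∪ b|`, defined as 1 when both sets are empty. Used here to
#' compare the missing-feature sets of two batches: batches that miss the
#' same features are similar and should be blocked together.
#'
#' @param a,b Vectors interpreted as sets.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    return(1)
  }
  length(intersect(a, b)) / u
}

#' Order batches before blocking
#'
#' Reorders batches so that blocking groups compatible neighbours, which
#' limits the data loss incurred when a blocked batch lacks sufficient values.
#' Three orderings are available:
#' \describe{
#'   \item{`sparsity`}{ascending count of missing cells, i.e. most complete
#'     batch first, ties broken by original batch index;}
#'   \item{`jaccard`}{a greedy chain started at the most complete batch,
#'     repeatedly appending the unplaced batch whose missing-feature set has
#'     the highest Jaccard similarity to the last placed batch (ties by
#'     lowest original index);}
#'   \item{`seriation`}{the leaf order of average-linkage hierarchical
#'     clustering on Jaccard distances, refined by optimal leaf ordering so
#'     that the summed dissimilarity of adjacent batches is minimal.}
#' }
#' The missing-feature set of a batch is the set of features with fewer than
#' `min_count` observed values in it -- the complement of its presence column,
#' i.e. missingness at the same granularity the dissection uses.
#'
#' @param matrix Expression matrix in canonical column order.
#' @param design A `"batch_design"` aligned with the matrix columns.
#' @param method `"sparsity"`, `"seriation"` or `"jaccard"`.
#' @param min_count Sufficiency threshold used for the missing-feature sets.
#' @return An object of class `"batch_order"`: list with `order` (permutation
#'   of `1..n`), `inverse`, and `method`. All three methods are deterministic.
#' @export
sort_batches <- function(matrix, design, method = c("sparsity", "seriation", "jaccard"),
                         min_count = 2L) {
  method <- match.arg(method)
  batch <- .align_batches(matrix, design)
  n <- max(batch)
  if (n == 1L) {
    return(structure(list(order = 1L, inverse = 1L, method = method),
                     class = "batch_order"))
  }
  miss_cells <- vapply(seq_len(n), function(b) {
    sum(is.na(matrix[, batch == b, drop = FALSE]))
  }, numeric(1))
  ord <- switch(method,
    sparsity = order(miss_cells, seq_len(n)),
    jaccard = .jaccard_chain(matrix, batch, miss_cells, min_count),
    seriation = .seriation_order(matrix, batch, min_count))
  structure(list(order = as.integer(ord), inverse = order(ord), method = method),
            class = "batch_order")
}

#' @export
print.batch_order <- function(x, ...) {
  cat("batch order (", x$method, "): ", paste(x$order, collapse = " "), "\n", sep = "")
  invisible(x)
}

.missing_sets <- function(matrix, batch, min_count) {
  pres <- presence_table(matrix, batch, min_count)
  lapply(seq_len(ncol(pres)), function(b) which(!pres[, b]))
}

.jaccard_chain <- function(matrix, batch, miss_cells, min_count) {
  n <- max(batch)
  sets <- .missing_sets(matrix, batch, min_count)
  placed <- order(miss_cells, seq_len(n))[1L]   # start at the most complete batch
  remaining <- setdiff(seq_len(n), placed)
  while (length(remaining)) {
    last <- placed[length(placed)]
    sims <- vapply(remaining, function(b) jaccard_index(sets[[last]], sets[[b]]),
                   numeric(1))
    nxt <- remaining[order(-sims, remaining)[1L]]   # ties: lowest original index
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  placed
}

.seriation_order <- function(matrix, batch, min_count) {
  n <- max(batch)
  sets <- .missing_sets(matrix, batch, min_count)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- 1 - jaccard_index(sets[[i]], sets[[j]])
    }
  }
  if (n == 2L) {
    return(1:2)
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ord <- .optimal_leaf_order(hc, D)
  # orientation is free: fix it deterministically
  if (.lex_less(rev(ord), ord)) rev(ord) else ord
}

.lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

## Optimal leaf ordering (Bar-Joseph style): among the orderings consistent
## with the dendrogram (subtree flips), minimize the summed distance between
## adjacent leaves. Dynamic programme over (first leaf, last leaf) endpoints.
.optimal_leaf_order <- function(hc, D) {
  entries <- function(v) {
    if (v < 0L) {
      return(list(list(first = -v, last = -v, cost = 0, ord = -v)))
    }
    ea <- entries(hc$merge[v, 1L])
    eb <- entries(hc$merge[v, 2L])
    best <- list()
    consider <- function(x, y) {
      for (l in x) {
        for (r in y) {
          cost <- l$cost + D[l$last, r$first] + r$cost
          key <- paste(l$first, r$last)
          cur <- best[[key]]
          ord <- c(l$ord, r$ord)
          if (is.null(cur) || cost < cur$cost ||
              (cost == cur$cost && .lex_less(ord, cur$ord))) {
            best[[key]] <<- list(first = l$first, last = r$last,
                                 cost = cost, ord = ord)
          }
        }
      }
    }
    consider(ea, eb)
    consider(eb, ea)
    best
  }
  root <- entries(nrow(hc$merge))
  costs <- vapply(root, `[[`, numeric(1), "cost")
  cands <- root[costs == min(costs)]
  ord <- cands[[1L]]$ord
  for (e in cands[-1L]) {
    if (.lex_less(e$ord, ord)) ord <- e$ord
  }
  ord
}

#' Partition ordered batches into blocks
#'
#' Groups `block` consecutive batches (along the given order) into one unit
#' for the dissection. A remainder of `n %% block` batches forms one smaller
#' trailing block of its own. `block = 1` reproduces unblocked behaviour;
#' `block = n` merges all batches into a single unit.
#'
#' @param order A `"batch_order"` or an integer permutation of `1..n`.
#' @param block Block size, between 1 and `n`.
#' @return An object of class `"block_map"`: list with `blocks` (ordered list
#'   of integer vectors of batch indices) and `block_size`.
#' @export
block_batches <- function(order, block) {
  ord <- if (inherits(order, "batch_order")) order$order else as.integer(order)
  n <- length(ord)
  block <- as.integer(block)
  if (block < 1L || block > n) {
    stop("block must be between 1 and the number of batches (", n, ")")
  }
  blocks <- unname(split(ord, ceiling(seq_len(n) / block)))
  structure(list(blocks = blocks, block_size = block), class = "block_map")
}

#' @export
print.block_map <- function(x, ...) {
  cat("block map (size ", x$block_size, "): ",
      paste(vapply(x$blocks, function(b) paste0("[", paste(b, collapse = " "), "]"),
                   character(1)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Collapse a batch presence table to block granularity
#'
#' A feature is present in a block only when it is present in *every* member
#' batch: if one blocked batch lacks sufficient values for a feature, the
#' whole block is unavailable for that feature (the price paid for the
#' smaller combination space).
#'
#' @param presence Logical features x batches table from [presence_table()].
#' @param blockmap A `"block_map"`.
#' @return Logical features x blocks matrix.
#' @export
blocked_presence <- function(presence, blockmap) {
  stopifnot(inherits(blockmap, "block_map"))
  out <- vapply(blockmap$blocks, function(bb) {
    rowSums(presence[, bb, drop = FALSE]) == length(bb)
  }, logical(nrow(presence)))
  if (nrow(presence) == 1L) {
    out <- matrix(out, nrow = 1L)
  }
  dimnames(out) <- list(rownames(presence), seq_along(blockmap$blocks))
  out
}
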