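# Shared fixtures and independent brute-force oracles.

make_design <- function(batch, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(batch))
  data.frame(ID = ids, sample = seq_along(batch), batch = batch,
             stringsAsFactors = FALSE)
}

named_matrix <- function(values, nrow, ncol) {
  matrix(values, nrow, ncol,
         dimnames = list(sprintf("f%04d", seq_len(nrow)),
                         sprintf("s%03d", seq_len(ncol))))
}

# random matrix with uniform missingness, batches contiguous
rand_missing_matrix <- function(G, batch, miss = 0.3, seed = 1) {
  set.seed(seed)
  N <- length(batch)
  X <- named_matrix(rnorm(G * N, 10, 2), G, N)
  X[matrix(runif(G * N) < miss, G, N)] <- NA
  X
}

# Brute-force presence: naive per-cell loops, no shared code with the package.
brute_presence <- function(X, batch, min_count = 2) {
  n <- max(batch)
  out <- matrix(FALSE, nrow(X), n)
  for (i in seq_len(nrow(X))) {
    for (b in seq_len(n)) {
      cnt <- 0
      for (j in which(batch == b)) {
        if (!is.na(X[i, j])) cnt <- cnt + 1
      }
      out[i, b] <- cnt >= min_count
    }
  }
  rownames(out) <- rownames(X)
  out
}

# Brute-force dissection: group features by the exact string key of their
# presence pattern; a group is adjustable when it spans >= 2 actual batches.
brute_dissect <- function(X, batch, min_count = 2, blocks = NULL) {
  pres <- brute_presence(X, batch, min_count)
  if (!is.null(blocks)) {
    bp <- matrix(FALSE, nrow(X), length(blocks))
    for (i in seq_len(nrow(X))) {
      for (k in seq_along(blocks)) {
        bp[i, k] <- all(pres[i, blocks[[k]]])
      }
    }
    pres <- bp
    unit_batches <- blocks
  } else {
    unit_batches <- as.list(seq_len(max(batch)))
  }
  keys <- apply(pres, 1, function(r) paste(which(r), collapse = ","))
  groups <- list()
  unadjustable <- character(0)
  for (i in seq_len(nrow(X))) {
    members <- unlist(unit_batches[which(pres[i, ])])
    if (length(members) >= 2) {
      groups[[keys[i]]] <- c(groups[[keys[i]]], rownames(X)[i])
    } else {
      unadjustable <- c(unadjustable, rownames(X)[i])
    }
  }
  cols <- lapply(names(groups), function(key) {
    units <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    sort(which(batch %in% unlist(unit_batches[units])))
  })
  names(cols) <- names(groups)
  list(groups = groups, columns = cols, unadjustable = unadjustable)
}

# compare a dissection_plan against the brute-force oracle
expect_plan_matches_brute <- function(plan, oracle) {
  plan_groups <- lapply(plan$submatrices, `[[`, "feature_ids")
  names(plan_groups) <- vapply(plan$submatrices, function(s)
    paste(s$combination, collapse = ","), character(1))
  expect_setequal(names(plan_groups), names(oracle$groups))
  for (key in names(oracle$groups)) {
    expect_identical(plan_groups[[key]], oracle$groups[[key]])
  }
  plan_cols <- lapply(plan$submatrices, `[[`, "columns")
  names(plan_cols) <- names(plan_groups)
  for (key in names(oracle$groups)) {
    expect_identical(sort(plan_cols[[key]]), oracle$columns[[key]])
  }
  expect_setequal(plan$unadjustable$feature, oracle$unadjustable)
}
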