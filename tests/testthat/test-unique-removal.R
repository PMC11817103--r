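test_that("unique combinations are those with multiplicity one among adjustable ones", {
  combos <- list(f1 = c(1L, 2L), f2 = c(1L, 2L), f3 = c(1L, 2L),
                 f4 = c(1L, 3L), f5 = 2L, f6 = integer(0))
  u <- find_unique(combos)
  expect_identical(names(u), "f4")      # f5/f6 are unadjustable, not unique
  expect_length(find_unique(list(a = 1:2, b = 1:2)), 0)
  all_distinct <- list(a = c(1L, 2L), b = c(1L, 3L), c = c(2L, 3L))
  expect_identical(names(find_unique(all_distinct)), c("a", "b", "c"))
})

test_that("crop choice minimizes batches removed, then maximizes values kept", {
  # larger subset anchor wins
  expect_identical(choose_crop(1:4, list(c(1L, 2L, 3L), c(1L, 2L)),
                               c(5, 5, 5, 5)),
                   c(1L, 2L, 3L))
  # tie on size: feature has 4 values in batch 1 and 2 in batch 3 -> keep batch 1
  expect_identical(choose_crop(1:3, list(c(1L, 2L), c(2L, 3L)),
                               c(4, 3, 2)),
                   c(1L, 2L))
  # tie on size and on values: lexicographically smallest combination
  expect_identical(choose_crop(1:3, list(c(2L, 3L), c(1L, 2L)),
                               c(2, 3, 2)),
                   c(1L, 2L))
  # no subset candidate
  expect_null(choose_crop(c(1L, 2L), list(c(3L, 4L)), c(2, 2, 2, 2)))
  # a candidate equal in size to the combination is no crop at all
  expect_null(choose_crop(c(1L, 2L), list(c(1L, 2L)), c(2, 2)))
})

test_that("unique removal crops to subset anchors and shrinks the dissection by one each", {
  batch <- rep(1:4, each = 3)
  X <- named_matrix(rnorm(7 * 12), 7, 12)
  X[1:2, batch == 4] <- NA              # {1,2,3} x2 (anchor)
  X[3:4, batch %in% c(3, 4)] <- NA      # {1,2} x2 (anchor)
                                        # f0005 complete: {1,2,3,4}, unique
  X[6, batch == 3] <- NA                # f0006: {1,2,4}, unique
  X[7, batch %in% c(1, 2)] <- NA        # f0007: {3,4}, unique, no anchor
  d <- make_design(batch, colnames(X))
  combos <- apply(presence_table(X, batch), 1, feature_combination, simplify = FALSE)
  res <- apply_unique_removal(X, combos, d)
  # f0005 crops one batch to reach {1,2,3}; f0006 has only the {1,2} anchor
  expect_identical(res$combinations[[5]], c(1L, 2L, 3L))
  expect_identical(res$combinations[[6]], c(1L, 2L))
  expect_identical(names(res$unresolved), "f0007")
  # dissection shrinks by exactly one sub-matrix per resolved feature
  count_keys <- function(cc) length(unique(vapply(cc[lengths(cc) >= 2],
                                                  paste, character(1), collapse = ",")))
  expect_identical(count_keys(res$combinations),
                   count_keys(combos) - nrow(res$crop_records))
  expect_identical(nrow(res$crop_records), 2L)
  # conservation: cells outside cropped (feature, batch) pairs are bit-identical
  for (i in c(1:4, 7)) {
    expect_identical(res$matrix[i, ], X[i, ])
  }
  expect_identical(res$matrix[5, batch %in% 1:3], X[5, batch %in% 1:3])
  expect_true(all(is.na(res$matrix[5, batch == 4])))
  expect_identical(res$crop_records$values_discarded[
    res$crop_records$feature == "f0005"], 3L)
})

test_that("two unique features may crop into the same existing combination", {
  batch <- rep(1:4, each = 3)
  X <- named_matrix(rnorm(6 * 12), 6, 12)
  X[1:2, batch %in% c(3, 4)] <- NA      # {1,2} x2 (anchor)
  X[3, batch == 3] <- NA                # {1,2,4} unique
  X[4, batch == 4] <- NA                # {1,2,3} unique
                                        # f0005, f0006 complete: {1,2,3,4} x2
  combos <- apply(presence_table(X, batch), 1, feature_combination, simplify = FALSE)
  res <- apply_unique_removal(X, combos, make_design(batch, colnames(X)))
  expect_identical(res$combinations[[3]], c(1L, 2L))
  expect_identical(res$combinations[[4]], c(1L, 2L))
  expect_identical(nrow(res$crop_records), 2L)
})

test_that("no unique features means the identity", {
  batch <- rep(1:3, each = 3)
  X <- named_matrix(rnorm(27), 3, 9)
  combos <- apply(presence_table(X, batch), 1, feature_combination, simplify = FALSE)
  res <- apply_unique_removal(X, combos, make_design(batch, colnames(X)))
  expect_identical(res$matrix, X)
  expect_identical(res$combinations, combos)
  expect_identical(nrow(res$crop_records), 0L)
})

test_that("unresolvable unique features are reported, not cropped", {
  batch <- rep(1:4, each = 3)
  X <- named_matrix(rnorm(3 * 12), 3, 12)
  X[1, batch %in% c(3, 4)] <- NA    # {1,2}
  X[2, batch %in% c(1, 2)] <- NA    # {3,4}: unique, no subset anchor
  X[3, batch %in% c(3, 4)] <- NA    # {1,2}
  combos <- apply(presence_table(X, batch), 1, feature_combination, simplify = FALSE)
  res <- apply_unique_removal(X, combos, make_design(batch, colnames(X)))
  expect_identical(names(res$unresolved), "f0002")
  expect_identical(res$matrix, X)
})

test_that("crop records are independent of feature order", {
  batch <- rep(1:5, each = 3)
  X <- rand_missing_matrix(40, batch, miss = 0.45, seed = 77)
  d <- make_design(batch, colnames(X))
  combos <- apply(presence_table(X, batch), 1, feature_combination, simplify = FALSE)
  res <- apply_unique_removal(X, combos, d)
  set.seed(5)
  sh <- sample(nrow(X))
  res_sh <- apply_unique_removal(X[sh, ], combos[sh], d)
  a <- res$crop_records[order(res$crop_records$feature), ]
  b <- res_sh$crop_records[order(res_sh$crop_records$feature), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("chosen crops are maximal: no larger population subset exists", {
  for (seed in 1:6) {
    batch <- rep(1:6, each = 3)
    X <- rand_missing_matrix(50, batch, miss = 0.5, seed = seed)
    combos <- apply(presence_table(X, batch), 1, feature_combination,
                    simplify = FALSE)
    res <- apply_unique_removal(X, combos, make_design(batch, colnames(X)))
    rec <- res$crop_records
    pool <- combos[setdiff(seq_along(combos), find_unique(combos))]
    for (r in seq_len(nrow(rec))) {
      orig <- as.integer(strsplit(rec$original[r], ",")[[1]])
      crop <- as.integer(strsplit(rec$cropped[r], ",")[[1]])
      # brute force over the anchor population: any strictly larger subset?
      for (cc in pool) {
        if (length(cc) >= 2 && length(cc) < length(orig) && all(cc %in% orig)) {
          expect_lte(length(cc), length(crop))
        }
      }
    }
  }
})
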