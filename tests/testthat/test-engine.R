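test_that("a complete matrix with one sub-matrix equals a direct kernel call", {
  set.seed(23)
  batch <- rep(1:3, each = 4)
  X <- named_matrix(rnorm(60 * 12, 10), 60, 12) +
    matrix(c(0, 1, -2)[batch], 60, 12, byrow = TRUE)
  d <- make_design(batch, colnames(X))
  res <- harmonize(X, d, algorithm = "limma", ur = FALSE, verbose = FALSE)
  expect_equal(res$matrix, limma_adjust(X, batch), tolerance = 1e-12)
  res2 <- harmonize(X, d, algorithm = "ComBat", ur = FALSE, verbose = FALSE)
  expect_equal(res2$matrix, combat_adjust(X, batch), tolerance = 1e-12)
})

test_that("the pipeline output equals brute-force per-combination kernel calls", {
  batch <- rep(1:4, each = 4)
  X <- rand_missing_matrix(80, batch, miss = 0.35, seed = 29)
  d <- make_design(batch, colnames(X))
  res <- harmonize(X, d, algorithm = "limma", ur = FALSE, verbose = FALSE)

  oracle <- brute_dissect(X, batch)
  groups <- Filter(function(g) length(g) >= 2, oracle$groups)
  expected_rows <- sort(unlist(unname(groups)))
  expect_identical(sort(rownames(res$matrix)), expected_rows)
  for (key in names(groups)) {
    feats <- groups[[key]]
    cols <- oracle$columns[[key]]
    direct <- limma_adjust(X[feats, cols, drop = FALSE], batch[cols])
    expect_equal(res$matrix[feats, cols], direct, tolerance = 1e-12)
    # cells outside the combination stay missing
    expect_true(all(is.na(res$matrix[feats, setdiff(seq_len(ncol(X)), cols)])))
  }
})

test_that("output is bit-identical across worker counts", {
  batch <- rep(1:4, each = 4)
  X <- rand_missing_matrix(60, batch, miss = 0.3, seed = 31)
  d <- make_design(batch, colnames(X))
  r1 <- harmonize(X, d, workers = 1, verbose = FALSE)
  r2 <- harmonize(X, d, workers = 2, verbose = FALSE)
  r4 <- harmonize(X, d, workers = 4, verbose = FALSE)
  expect_identical(r1$matrix, r2$matrix)
  expect_identical(r1$matrix, r4$matrix)
})

test_that("row and column order of the input are restored", {
  set.seed(37)
  batch <- sample(rep(1:3, each = 4))      # interleaved batches
  X <- rand_missing_matrix(50, batch, miss = 0.25, seed = 41)
  d <- make_design(batch, colnames(X))
  res <- harmonize(X, d, verbose = FALSE)
  expect_identical(colnames(res$matrix), colnames(X))
  expect_identical(rownames(res$matrix),
                   rownames(X)[rownames(X) %in% rownames(res$matrix)])
  resb <- harmonize(X, d, block = 2, sort = "jaccard", verbose = FALSE)
  expect_identical(colnames(resb$matrix), colnames(X))
})

test_that("block = 1 output is invariant to the sorting method", {
  batch <- rep(1:5, each = 4)
  X <- rand_missing_matrix(60, batch, miss = 0.35, seed = 43)
  d <- make_design(batch, colnames(X))
  base <- harmonize(X, d, block = 1, sort = "off", verbose = FALSE)
  for (m in c("sparsity", "seriation", "jaccard")) {
    alt <- harmonize(X, d, block = 1, sort = m, verbose = FALSE)
    expect_identical(alt$matrix, base$matrix)
  }
  # sorting without blocking is a warned no-op
  expect_warning(noop <- harmonize(X, d, sort = "sparsity", verbose = FALSE),
                 "no effect without blocking")
  off <- harmonize(X, d, verbose = FALSE)
  expect_identical(noop$matrix, off$matrix)
})

test_that("report accounting is consistent", {
  batch <- rep(1:5, each = 3)
  X <- rand_missing_matrix(80, batch, miss = 0.45, seed = 47)
  d <- make_design(batch, colnames(X))
  res <- harmonize(X, d, verbose = FALSE, keep_unadjusted = TRUE)
  rep <- res$report
  expect_identical(rep$considered + nrow(rep$dropped), rep$total_features)
  expect_identical(rep$submatrices_before_ur - nrow(rep$crop_records),
                   rep$submatrices_after_ur)
  expect_identical(nrow(res$matrix), rep$total_features)
  res2 <- harmonize(X, d, verbose = FALSE)
  expect_identical(nrow(res2$matrix), res2$report$considered)
})

test_that("degenerate inputs raise errors", {
  X <- named_matrix(rnorm(40), 10, 4)
  expect_error(harmonize(X, make_design(rep(1, 4), colnames(X)), verbose = FALSE),
               "at least two batches")
  Y <- named_matrix(NA_real_, 5, 6)
  Y[, 1] <- 1   # one value per feature in batch 1 only
  expect_error(harmonize(Y, make_design(rep(1:2, each = 3), colnames(Y)),
                         verbose = FALSE),
               "no adjustable features")
})

test_that("the CLI wires flags through and reports usage errors", {
  batch <- rep(1:3, each = 4)
  X <- rand_missing_matrix(40, batch, miss = 0.2, seed = 53)
  d <- make_design(batch, colnames(X))
  fm <- withr::local_tempfile(fileext = ".tsv")
  fd <- withr::local_tempfile(fileext = ".csv")
  fo <- withr::local_tempfile(fileext = ".tsv")
  fr <- withr::local_tempfile(fileext = ".txt")
  write_matrix(X, fm)
  writeLines(c("ID,sample,batch",
               paste(d$ID, d$sample, d$batch, sep = ",")), fd)
  code <- suppressMessages(run_cli(c("--data", fm, "--description", fd,
                                     "--output", fo, "--algorithm", "limma",
                                     "--report", fr)))
  expect_identical(code, 0L)
  out <- read_matrix(fo)
  ref <- harmonize(X, d, algorithm = "limma", verbose = FALSE)
  expect_equal(out, ref$matrix, tolerance = 1e-12)
  expect_true(any(grepl("considered", readLines(fr))))

  expect_identical(suppressMessages(run_cli(c("--data", fm))), 2L)
  expect_identical(suppressMessages(
    run_cli(c("--data", fm, "--description", fd, "--output", fo,
              "--sort", "badname"))), 2L)
  expect_identical(suppressMessages(
    run_cli(c("--data", "/nonexistent/m.tsv", "--description", fd,
              "--output", fo))), 1L)
})
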