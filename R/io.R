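#' Read an expression matrix from delimited text
#'
#' Parses a feature-by-sample expression matrix from a delimited text file.
#' The first row is a header of sample identifiers (optionally preceded by a
#' name for the feature-identifier column) and the first column holds feature
#' identifiers. Empty cells and the tokens `NA` / `NaN` (case-insensitive)
#' parse as missing values; every other cell must parse as a finite real.
#'
#' @param path Path to the file.
#' @param delimiter Field separator, `"\t"` (default) or `","`.
#'
#' @return A numeric matrix with feature identifiers as row names and sample
#'   identifiers as column names. Missing entries are `NA`. Row and column
#'   order follow the file.
#'
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("ID\ts1\ts2", "p1\t1.5\t", "p2\t2\t3"), f)
#' m <- read_matrix(f)
#' sum(is.na(m))
#' @seealso [write_matrix()], [read_description()]
#' @export
read_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop("empty file: ", path)
  }
  fields <- .split_keep_empty(lines, delimiter)
  header <- fields[[1L]]
  body <- fields[-1L]
  n_body_fields <- if (length(body)) lengths(body) else integer(0)
  if (length(body) && length(unique(n_body_fields)) != 1L) {
    stop("ragged rows: lines differ in field count")
  }
  nfield <- if (length(body)) n_body_fields[1L] else length(header)
  if (length(header) == nfield) {
    sample_ids <- header[-1L]            # header names the feature-ID column
  } else if (length(header) == nfield - 1L) {
    sample_ids <- header                 # bare header of sample IDs only
  } else {
    stop("header field count does not match data rows")
  }
  feature_ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  values <- matrix(NA_real_, length(feature_ids), length(sample_ids),
                   dimnames = list(feature_ids, sample_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    values[i, ] <- .parse_cells(cells, feature_ids[i], sample_ids)
  }
  values
}

## strsplit drops trailing empty fields, which encode missing values here;
## a sentinel suffix keeps them
.split_keep_empty <- function(lines, delimiter) {
  out <- strsplit(paste0(lines, delimiter, "\x01"), delimiter, fixed = TRUE)
  lapply(out, function(f) f[-length(f)])
}

## missing tokens accepted on input: "", "NA", "NaN" (case-insensitive)
.parse_cells <- function(cells, feature_id, sample_ids) {
  cells <- trimws(cells)
  miss <- tolower(cells) %in% c("", "na", "nan")
  out <- rep(NA_real_, length(cells))
  if (any(!miss)) {
    num <- suppressWarnings(as.numeric(cells[!miss]))
    bad <- !is.finite(num)
    if (any(bad)) {
      j <- which(!miss)[which(bad)[1L]]
      stop("non-numeric cell at feature '", feature_id, "', sample '",
           sample_ids[j], "': '", cells[j], "'")
    }
    out[!miss] <- num
  }
  out
}

#' Write an expression matrix to delimited text
#'
#' Missing entries are serialized as `NA`; finite values are written with
#' enough digits to round-trip exactly through [read_matrix()].
#'
#' @param matrix Numeric matrix with row and column names.
#' @param path Output file path.
#' @param delimiter Field separator, `"\t"` (default) or `","`.
#' @return Invisibly, `path`.
#' @seealso [read_matrix()]
#' @export
write_matrix <- function(matrix, path, delimiter = "\t") {
  stopifnot(is.matrix(matrix))
  header <- paste(c("ID", colnames(matrix)), collapse = delimiter)
  if (nrow(matrix) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  cells <- ifelse(is.na(matrix), "NA", sprintf("%.17g", matrix))
  rows <- apply(cbind(rownames(matrix), cells), 1L, paste, collapse = delimiter)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a batch description table
#'
#' The description assigns every sample of the expression matrix to a batch.
#' It is a delimited text file with a header and three columns: sample
#' identifier, sample ordinal (position of the sample's column), and batch
#' label (integer). Batch labels need not be contiguous or start at one; they
#' are normalized downstream by [canonicalize_design()].
#'
#' @param path Path to the file.
#' @param delimiter Field separator; `NULL` (default) sniffs tab versus comma
#'   from the first line.
#' @return A `data.frame` with columns `ID` (character), `sample` (integer)
#'   and `batch` (integer).
#' @export
read_description <- function(path, delimiter = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (is.null(delimiter)) {
    first <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L) {
    stop("description must have three columns: ID, sample, batch")
  }
  out <- data.frame(ID = as.character(tab[[1L]]),
                    sample = .as_integerish(tab[[2L]], "sample ordinal"),
                    batch = .as_integerish(tab[[3L]], "batch"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$ID)) {
    stop("duplicate sample IDs in description")
  }
  if (any(out$batch < 1L) || any(out$sample < 1L)) {
    stop("sample ordinals and batch labels must be positive integers")
  }
  out
}

.as_integerish <- function(x, what) {
  num <- suppressWarnings(as.numeric(trimws(x)))
  if (any(!is.finite(num)) || any(num != round(num))) {
    stop("non-integer ", what, ": '", x[which(!is.finite(num) | num != round(num))[1L]], "'")
  }
  as.integer(num)
}

#' Canonicalize a batch design against an expression matrix
#'
#' Normalizes batch labels to the contiguous set `1..n` in order of first
#' appearance, and computes the stable column permutation that makes the
#' samples of each batch occupy contiguous columns. The permutation is
#' recorded so the original column order can be restored after adjustment.
#'
#' @param matrix Expression matrix (features x samples) with column names.
#' @param design Batch description `data.frame` as returned by
#'   [read_description()], or any data frame whose first three columns are
#'   sample ID, sample ordinal and batch.
#' @return An object of class `"batch_design"`: a list with elements
#'   \describe{
#'     \item{batch}{integer batch index (1..n) per canonical column,}
#'     \item{n_batches}{number of batches `n`,}
#'     \item{perm}{permutation such that `matrix[, perm]` is canonical,}
#'     \item{inv_perm}{inverse permutation restoring the input order,}
#'     \item{original_labels}{original batch label for each normalized index,}
#'     \item{sample_ids}{canonical (reordered) sample identifiers.}
#'   }
#' @details Canonicalization is idempotent: applying it to an
#'   already-contiguous design yields the identity permutation.
#' @export
canonicalize_design <- function(matrix, design) {
  stopifnot(is.matrix(matrix))
  if (is.null(colnames(matrix))) {
    stop("matrix must have sample IDs as column names")
  }
  if (inherits(design, "batch_design")) {
    return(design)
  }
  ids <- as.character(design[[1L]])
  batch_raw <- .as_integerish(design[[3L]], "batch")
  missing_in_desc <- setdiff(colnames(matrix), ids)
  if (length(missing_in_desc)) {
    stop("samples absent from description: ",
         paste(missing_in_desc, collapse = ", "))
  }
  missing_in_mat <- setdiff(ids, colnames(matrix))
  if (length(missing_in_mat)) {
    stop("description samples absent from matrix: ",
         paste(missing_in_mat, collapse = ", "))
  }
  batch_by_col <- batch_raw[match(colnames(matrix), ids)]
  labels <- unique(batch_by_col)                  # first-appearance order
  norm <- match(batch_by_col, labels)
  perm <- order(norm, seq_along(norm))            # stable within batch
  structure(list(batch = norm[perm],
                 n_batches = length(labels),
                 perm = perm,
                 inv_perm = order(perm),
                 original_labels = labels,
                 sample_ids = colnames(matrix)[perm]),
            class = "batch_design")
}

## Batch index per column of `matrix`, in the matrix's own column order.
## Accepts an integer vector, a description data frame (canonicalized against
## the matrix), or a "batch_design" already aligned with the columns.
.align_batches <- function(matrix, design) {
  if (inherits(design, "batch_design")) {
    stopifnot(length(design$batch) == ncol(matrix))
    design$batch
  } else if (is.data.frame(design)) {
    cd <- canonicalize_design(matrix, design)
    cd$batch[cd$inv_perm]
  } else {
    batch <- as.integer(design)
    stopifnot(length(batch) == ncol(matrix))
    batch
  }
}

#' @export
print.batch_design <- function(x, ...) {
  cat("batch design:", length(x$batch), "samples in", x$n_batches, "batches\n")
  cat("batch sizes:", paste(tabulate(x$batch), collapse = " "), "\n")
  invisible(x)
}
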