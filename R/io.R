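#' Read a fingerprint dataset from disk
#'
#' Two plain-text dialects are supported:
#'
#' * `sparse-tsv`: a header line `#width=<B>` followed by one record per
#'   line, `<molecule_id>\t<idx>:<count>[,<idx>:<count>]*`. An empty second
#'   field encodes a molecule with no fragments.
#' * `dense-csv`: header `id,f0,f1,...,f<B-1>` and one integer row per
#'   molecule; zero cells are dropped on load.
#'
#' @param path file to read.
#' @param format `"sparse-tsv"` or `"dense-csv"`.
#' @return an [fp_dataset()] preserving file row order.
#' @export
read_fp_dataset <- function(path, format = c("sparse-tsv", "dense-csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (format == "sparse-tsv") read_sparse_tsv(path) else read_dense_csv(path)
}

read_sparse_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || !startsWith(lines[1L], "#width="))
    stop(sprintf("%s: missing '#width=' header", path), call. = FALSE)
  width <- suppressWarnings(as.integer(sub("^#width=", "", lines[1L])))
  if (is.na(width) || width < 1L)
    stop(sprintf("%s: invalid width header", path), call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  n <- length(body)
  ids <- character(n)
  ii <- vector("list", n)
  cc <- vector("list", n)
  for (k in seq_len(n)) {
    parts <- strsplit(body[k], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 1L || length(parts) > 2L || !nzchar(parts[1L]))
      stop(sprintf("%s: malformed record at line %d", path, k + 1L),
           call. = FALSE)
    ids[k] <- parts[1L]
    field <- if (length(parts) == 2L) parts[2L] else ""
    if (!nzchar(field)) {
      ii[[k]] <- integer()
      cc[[k]] <- numeric()
      next
    }
    toks <- strsplit(field, ",", fixed = TRUE)[[1L]]
    m <- regmatches(toks, regexec("^([0-9]+):([0-9]+)$", toks))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad))
      stop(sprintf("%s: malformed fragment entry at line %d", path, k + 1L),
           call. = FALSE)
    idx <- as.integer(vapply(m, `[`, character(1), 2L))
    cnt <- as.numeric(vapply(m, `[`, character(1), 3L))
    if (any(idx >= width))
      stop(sprintf("%s: fragment index >= width at line %d", path, k + 1L),
           call. = FALSE)
    if (any(cnt < 1))
      stop(sprintf("%s: non-positive count at line %d", path, k + 1L),
           call. = FALSE)
    if (anyDuplicated(idx))
      stop(sprintf("%s: duplicate fragment index at line %d", path, k + 1L),
           call. = FALSE)
    ii[[k]] <- idx
    cc[[k]] <- cnt
  }
  check_ids(ids)
  nnz <- lengths(ii)
  mat <- sparse_counts(i = rep.int(seq_len(n), nnz),
                       j = unlist(ii, use.names = FALSE) + 1L,
                       x = unlist(cc, use.names = FALSE),
                       dims = c(n, width))
  new_fp_dataset(mat, ids, width)
}

read_dense_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2L || names(df)[1L] != "id")
    stop(sprintf("%s: dense-csv requires an 'id' first column", path),
         call. = FALSE)
  width <- ncol(df) - 1L
  expect <- paste0("f", seq_len(width) - 1L)
  if (!identical(names(df)[-1L], expect))
    stop(sprintf("%s: dense-csv header must be id,f0,...,f%d", path,
                 width - 1L), call. = FALSE)
  ids <- as.character(df[[1L]])
  check_ids(ids)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(m) || any(m < 0))
    stop(sprintf("%s: cells must be non-negative integers", path),
         call. = FALSE)
  new_fp_dataset(as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    "CsparseMatrix"),
                 ids, width)
}

#' Write a fingerprint dataset to disk
#'
#' The inverse of [read_fp_dataset()]; sparse records list fragments in
#' ascending index order so output is canonical and byte-reproducible.
#'
#' @param dataset an [fp_dataset()].
#' @param path file to write.
#' @inheritParams read_fp_dataset
#' @export
write_fp_dataset <- function(dataset, path,
                             format = c("sparse-tsv", "dense-csv")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "fp_dataset"))
  if (format == "sparse-tsv") {
    tm <- as(dataset$mat, "TsparseMatrix")
    fields <- character(length(dataset$ids))
    if (length(tm@x)) {
      o <- order(tm@i, tm@j)
      ent <- sprintf("%d:%g", tm@j[o], tm@x[o])
      grp <- tm@i[o] + 1L
      agg <- vapply(split(ent, grp), paste, character(1), collapse = ",")
      fields[as.integer(names(agg))] <- agg
    }
    lines <- c(sprintf("#width=%d", dataset$width),
               paste(dataset$ids, fields, sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    m <- as.matrix(dataset$mat)
    df <- data.frame(id = dataset$ids, m, check.names = FALSE)
    names(df) <- c("id", paste0("f", seq_len(dataset$width) - 1L))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write activity-class membership tables
#'
#' An activity table is a two-column tab-separated file,
#' `molecule_id\tclass_id`, one row per class member.
#'
#' @param path file to read or write.
#' @return `read_activity_table()` returns a data.frame with character
#'   columns `molecule_id` and `class_id`.
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("molecule_id", "class_id") %in% names(df)))
    stop(sprintf("%s: expected columns molecule_id and class_id", path),
         call. = FALSE)
  df[, c("molecule_id", "class_id")]
}

#' @rdname read_activity_table
#' @param activity data.frame with columns `molecule_id`, `class_id`.
#' @export
write_activity_table <- function(activity, path) {
  stopifnot(all(c("molecule_id", "class_id") %in% names(activity)))
  utils::write.table(activity[, c("molecule_id", "class_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils read.delim
NULL

# Split an activity table into a named list class_id -> member ids,
# validating referential integrity against a dataset.
activity_classes <- function(activity, dataset = NULL) {
  cls <- split(activity$molecule_id, activity$class_id)
  if (!is.null(dataset)) {
    missing <- setdiff(activity$molecule_id, dataset$ids)
    if (length(missing))
      stop(sprintf("activity table references unknown molecule_id: %s",
                   missing[1L]), call. = FALSE)
  }
  cls[order(names(cls))]
}
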