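#' Collection statistics for the Okapi belief function
#'
#' Computes, from a fingerprint database, the collection-wide quantities
#' the Okapi belief needs: the number of compounds `m`, the per-fragment
#' collection frequency `cf` (number of compounds containing each
#' fragment), the per-compound size `|c_j|`, and the mean compound size
#' `c_avg`.
#'
#' Compound size can be counted two ways, because count fingerprints admit
#' both readings of "number of fragments":
#' * `total-count` (default): the sum of all occurrence counts, the direct
#'   analogue of document length in token-based retrieval;
#' * `unique-fragments`: the number of distinct fragments present.
#'
#' @param dataset a non-empty [fp_dataset()].
#' @param size_mode `"total-count"` or `"unique-fragments"`.
#' @return an object of class `corpus_stats` with fields `m`, `width`,
#'   `cf` (length-`width` vector, 0 for absent fragments), `sizes` (named
#'   by molecule id), `c_avg` and `size_mode`.
#' @export
corpus_stats <- function(dataset, size_mode = c("total-count",
                                                "unique-fragments")) {
  size_mode <- match.arg(size_mode)
  stopifnot(inherits(dataset, "fp_dataset"))
  m <- length(dataset$ids)
  if (m == 0L) stop("dataset is empty", call. = FALSE)
  b <- dataset$mat
  b@x[] <- 1
  cf <- Matrix::colSums(b)
  sizes <- if (size_mode == "total-count") Matrix::rowSums(dataset$mat)
           else Matrix::rowSums(b)
  names(sizes) <- dataset$ids
  structure(list(m = m, width = dataset$width, cf = as.numeric(cf),
                 sizes = sizes, c_avg = mean(sizes), size_mode = size_mode,
                 checksum = dataset_checksum(dataset)),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf(paste0("<corpus_stats> m=%d compounds, width=%d, ",
                     "%d fragment(s) seen, c_avg=%.4f (%s)\n"),
              x$m, x$width, sum(x$cf > 0), x$c_avg, x$size_mode))
  invisible(x)
}

# Cheap deterministic content checksum used to invalidate cached statistics.
dataset_checksum <- function(dataset) {
  h <- (length(dataset$ids) * 31 + dataset$width) %% .MOD31
  for (id in dataset$ids) h <- (h * 31 + sum(utf8ToInt(id))) %% .MOD31
  tm <- as(dataset$mat, "TsparseMatrix")
  if (length(tm@x)) {
    o <- order(tm@i, tm@j)
    v <- (as.numeric(tm@i[o]) * 1031 + as.numeric(tm@j[o]) * 97 +
            as.numeric(tm@x[o])) %% .MOD31
    for (chunk in split(v, ceiling(seq_along(v) / 4096)))
      h <- (h * 48271 + sum(chunk)) %% .MOD31
  }
  sprintf("%d", as.integer(h))
}

#' Cache corpus statistics in a tab-separated sidecar file
#'
#' The sidecar records `m`, `c_avg`, the size mode, a dataset checksum and
#' one `idx\tcf` line per fragment present in the collection. On load the
#' checksum is compared with the dataset's and per-compound sizes are
#' recomputed; a mismatch invalidates the cache.
#'
#' @param stats a [corpus_stats()] object.
#' @param path sidecar file path.
#' @export
write_corpus_stats <- function(stats, path) {
  stopifnot(inherits(stats, "corpus_stats"))
  nz <- which(stats$cf > 0)
  lines <- c(sprintf("#m=%d", stats$m),
             sprintf("#cavg=%.17g", stats$c_avg),
             sprintf("#size_mode=%s", stats$size_mode),
             sprintf("#checksum=%s", stats$checksum),
             sprintf("%d\t%g", nz - 1L, stats$cf[nz]))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_stats
#' @param dataset the [fp_dataset()] the cache was computed from.
#' @return `read_corpus_stats()` returns the cached [corpus_stats()];
#'   it fails if the cache does not match the dataset.
#' @export
read_corpus_stats <- function(path, dataset) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  hdr <- function(key) {
    l <- lines[startsWith(lines, paste0("#", key, "="))]
    if (length(l) != 1L)
      stop(sprintf("%s: missing header #%s=", path, key), call. = FALSE)
    sub(paste0("^#", key, "="), "", l)
  }
  checksum <- hdr("checksum")
  if (!identical(checksum, dataset_checksum(dataset)))
    stop(sprintf("%s: cache is stale (dataset checksum mismatch)", path),
         call. = FALSE)
  size_mode <- hdr("size_mode")
  m <- as.integer(hdr("m"))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  cf <- numeric(dataset$width)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    cf[as.integer(vapply(parts, `[`, character(1), 1L)) + 1L] <-
      as.numeric(vapply(parts, `[`, character(1), 2L))
  }
  # sizes are cheap and not part of the sidecar format: recompute from data
  sizes <- if (size_mode == "total-count") Matrix::rowSums(dataset$mat)
           else Matrix::rowSums(dataset$mat != 0)
  names(sizes) <- dataset$ids
  structure(list(m = m, width = dataset$width, cf = cf, sizes = sizes,
                 c_avg = as.numeric(hdr("cavg")), size_mode = size_mode,
                 checksum = checksum),
            class = "corpus_stats")
}
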