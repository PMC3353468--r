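#' Count fingerprints
#'
#' A count fingerprint (ECFC-style) maps hashed substructure fragment
#' indices to positive occurrence counts over a folded index space of a
#' fixed `width`. Fragment indices are 0-based and must lie in
#' `[0, width)`; zero counts are represented by absence.
#'
#' @param idx integer vector of fragment indices (0-based, `< width`),
#'   duplicates not allowed.
#' @param count numeric vector of positive occurrence counts, parallel to
#'   `idx`.
#' @param width fingerprint width (number of folded bins), default 1024.
#' @return an object of class `count_fp` with fields `width`, `idx`
#'   (sorted ascending) and `count`.
#' @examples
#' count_fp(c(5L, 7L), c(2, 1))
#' @export
count_fp <- function(idx = integer(), count = numeric(), width = 1024L) {
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 1L)
    stop("width must be a positive integer", call. = FALSE)
  idx <- as.integer(idx)
  count <- as.numeric(count)
  if (length(idx) != length(count))
    stop("idx and count must have equal length", call. = FALSE)
  if (anyNA(idx) || anyNA(count))
    stop("idx and count must not contain NA", call. = FALSE)
  if (length(idx)) {
    if (any(idx < 0L) || any(idx >= width))
      stop("fragment indices must lie in [0, width)", call. = FALSE)
    if (anyDuplicated(idx))
      stop("duplicate fragment indices", call. = FALSE)
    if (any(count <= 0))
      stop("all stored counts must be positive", call. = FALSE)
    o <- order(idx)
    idx <- idx[o]
    count <- count[o]
  }
  structure(list(width = width, idx = idx, count = count),
            class = "count_fp")
}

#' @export
print.count_fp <- function(x, ...) {
  cat(sprintf("<count_fp> width=%d, %d fragment(s), total count %g\n",
              x$width, length(x$idx), sum(x$count)))
  invisible(x)
}

#' Fold raw fragment counts into a fixed-width fingerprint
#'
#' Folding maps every raw fragment index `k` of the unbounded hash space to
#' the bin `k %% width`; counts of colliding indices are summed. This is the
#' standard construction of 1024-element folded count fingerprints.
#'
#' @param idx integer vector of raw (unfolded) fragment indices, non-negative
#'   but otherwise unbounded.
#' @param count parallel vector of positive counts.
#' @inheritParams count_fp
#' @return a [count_fp()].
#' @examples
#' fold_counts(c(5, 1029), c(2, 1), width = 1024)  # collides into bin 5
#' @export
fold_counts <- function(idx, count, width = 1024L) {
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 1L)
    stop("width must be a positive integer", call. = FALSE)
  idx <- as.numeric(idx)
  count <- as.numeric(count)
  if (length(idx) != length(count))
    stop("idx and count must have equal length", call. = FALSE)
  if (length(idx) == 0L) return(count_fp(width = width))
  if (anyNA(idx) || any(idx < 0) || any(idx != floor(idx)))
    stop("raw fragment indices must be non-negative integers", call. = FALSE)
  if (anyNA(count) || any(count <= 0))
    stop("raw counts must be positive", call. = FALSE)
  folded <- as.integer(idx %% width)
  agg <- rowsum(count, group = folded)
  count_fp(as.integer(rownames(agg)), as.numeric(agg), width = width)
}

#' Fingerprint datasets
#'
#' An ordered collection of uniquely identified molecules, each represented
#' by a [count_fp()] of a common width. Internally the counts are held as a
#' sparse molecules-by-width matrix so that whole-database scoring is a
#' handful of sparse linear-algebra operations.
#'
#' @param fps list of [count_fp()] objects, all of the same width.
#' @param ids character vector of unique molecule identifiers (no tab or
#'   newline characters), parallel to `fps`.
#' @param width fingerprint width; taken from the fingerprints when omitted.
#' @return an object of class `fp_dataset` with fields `width`, `ids` and
#'   `mat` (a `dgCMatrix`, rows in input order).
#' @export
fp_dataset <- function(fps, ids, width = NULL) {
  stopifnot(is.list(fps), length(fps) == length(ids))
  ids <- as.character(ids)
  check_ids(ids)
  if (is.null(width)) {
    if (length(fps) == 0L)
      stop("width must be given for an empty dataset", call. = FALSE)
    width <- fps[[1L]]$width
  }
  width <- as.integer(width)
  for (fp in fps) {
    if (!inherits(fp, "count_fp")) stop("fps must be count_fp objects",
                                        call. = FALSE)
    if (fp$width != width)
      stop("all fingerprint widths must equal the dataset width",
           call. = FALSE)
  }
  n <- length(fps)
  nnz <- vapply(fps, function(fp) length(fp$idx), integer(1))
  mat <- sparse_counts(
    i = rep.int(seq_len(n), nnz),
    j = unlist(lapply(fps, `[[`, "idx"), use.names = FALSE) + 1L,
    x = unlist(lapply(fps, `[[`, "count"), use.names = FALSE),
    dims = c(n, width))
  new_fp_dataset(mat, ids, width)
}

# sparseMatrix() cannot infer the storage kind from zero entries; build the
# empty dgCMatrix directly in that case.
sparse_counts <- function(i, j, x, dims) {
  if (length(x) == 0L)
    return(new("dgCMatrix", Dim = as.integer(dims),
               p = rep(0L, dims[2L] + 1L)))
  Matrix::sparseMatrix(i = as.integer(i), j = as.integer(j),
                       x = as.numeric(x), dims = dims)
}

new_fp_dataset <- function(mat, ids, width) {
  rownames(mat) <- ids
  structure(list(width = as.integer(width), ids = as.character(ids),
                 mat = mat),
            class = "fp_dataset")
}

check_ids <- function(ids) {
  if (any(!nzchar(ids)) || anyNA(ids))
    stop("molecule ids must be non-empty", call. = FALSE)
  if (any(grepl("[\t\n\r]", ids)))
    stop("molecule ids must not contain tab or newline characters",
         call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate molecule_id: %s", dup[1L]), call. = FALSE)
  invisible(ids)
}

#' @export
length.fp_dataset <- function(x) length(x$ids)

#' @export
print.fp_dataset <- function(x, ...) {
  cat(sprintf("<fp_dataset> %d molecule(s), width %d, %d stored count(s)\n",
              length(x$ids), x$width, length(x$mat@x)))
  invisible(x)
}

#' Extract one molecule's fingerprint from a dataset
#'
#' @param dataset an [fp_dataset()].
#' @param id molecule identifier.
#' @return a [count_fp()].
#' @export
get_fingerprint <- function(dataset, id) {
  i <- match(id, dataset$ids)
  if (is.na(i)) stop(sprintf("unknown molecule_id: %s", id), call. = FALSE)
  row <- dataset$mat[i, ]
  nz <- which(row != 0)
  count_fp(nz - 1L, row[nz], width = dataset$width)
}

#' Binary Tanimoto similarity of two count fingerprints
#'
#' The classical Tanimoto (Jaccard) coefficient on fragment
#' presence/absence: `|A intersect B| / |A union B|`. Two empty
#' fingerprints are identical objects and score 1 by convention.
#'
#' @param a,b [count_fp()] objects of equal width.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_binary <- function(a, b) {
  stopifnot(inherits(a, "count_fp"), inherits(b, "count_fp"))
  if (a$width != b$width) stop("fingerprint widths differ", call. = FALSE)
  if (length(a$idx) == 0L && length(b$idx) == 0L) return(1.0)
  inter <- length(intersect(a$idx, b$idx))
  inter / (length(a$idx) + length(b$idx) - inter)
}

#' Mean pairwise similarity of an activity class
#'
#' The diversity statistic attached to an activity class: the arithmetic
#' mean of the binary Tanimoto similarity over all unordered pairs of the
#' named members. Lower values indicate a more structurally heterogeneous
#' class.
#'
#' @param dataset an [fp_dataset()].
#' @param member_ids character vector of at least two molecule ids, all
#'   present in `dataset`.
#' @return mean pairwise similarity in `[0, 1]`.
#' @export
class_mean_similarity <- function(dataset, member_ids) {
  member_ids <- unique(as.character(member_ids))
  if (length(member_ids) < 2L)
    stop("at least 2 class members are required", call. = FALSE)
  i <- match(member_ids, dataset$ids)
  if (anyNA(i))
    stop(sprintf("unknown molecule_id: %s", member_ids[which(is.na(i))[1L]]),
         call. = FALSE)
  b <- dataset$mat[i, , drop = FALSE]
  b@x[] <- 1
  mean_pairwise_tanimoto(b)
}

# Mean off-diagonal Tanimoto of a sparse binary matrix (rows = molecules).
mean_pairwise_tanimoto <- function(b) {
  inter <- as.matrix(Matrix::tcrossprod(b))
  sz <- Matrix::rowSums(b)
  un <- outer(sz, sz, "+") - inter
  sim <- ifelse(un > 0, inter / un, 1)  # two empty fingerprints: identical
  n <- nrow(b)
  (sum(sim) - sum(diag(sim))) / (n * (n - 1))
}
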