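#' Continuous Tanimoto similarity of count fingerprints
#'
#' The continuous generalization of the Tanimoto coefficient for count
#' (non-binary) fingerprints:
#' \deqn{S_{k,l} = \frac{\sum_j w_{jk} w_{jl}}
#'   {\sum_j w_{jk}^2 + \sum_j w_{jl}^2 - \sum_j w_{jk} w_{jl}}}
#' It equals 1 exactly when the two fingerprints are identical and reduces
#' to the binary Tanimoto when every stored count is 1.
#'
#' @param a,b [count_fp()] objects of equal width, not both empty.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_continuous <- function(a, b) {
  stopifnot(inherits(a, "count_fp"), inherits(b, "count_fp"))
  if (a$width != b$width) stop("fingerprint widths differ", call. = FALSE)
  if (length(a$idx) == 0L && length(b$idx) == 0L)
    stop("both fingerprints are empty", call. = FALSE)
  common <- match(a$idx, b$idx)
  hit <- !is.na(common)
  dot <- sum(a$count[hit] * b$count[common[hit]])
  dot / (sum(a$count^2) + sum(b$count^2) - dot)
}

#' Okapi (BM25-style) belief of a fragment given a compound
#'
#' The per-fragment belief used at the fragment nodes of the Bayesian
#' inference network:
#' \deqn{bel = \alpha + (1-\alpha)\,
#'   \frac{ff_{ij}}{ff_{ij} + 0.5 + 1.5\,|c_j|/|C_{avg}|}\,
#'   \frac{\log((m+0.5)/cf_i)}{\log(m+1)}}
#' combining the fragment's within-compound frequency, compound-length
#' normalization and inverse collection frequency, offset by the baseline
#' `alpha`. The value is independent of the logarithm base and equals
#' `alpha` exactly when `ff = 0`.
#'
#' All frequency arguments are vectorized (recycled to a common length).
#'
#' @param ff within-compound frequency of the fragment (non-negative).
#' @param compound_size size `|c_j|` of the compound (non-negative).
#' @param cf number of compounds containing the fragment (at least 1).
#' @param m total number of compounds in the collection.
#' @param c_avg mean compound size of the collection (positive).
#' @param alpha baseline belief in `[0, 1)`, default 0.4.
#' @return belief value(s) in `[alpha, 1)`.
#' @export
okapi_belief <- function(ff, compound_size, cf, m, c_avg, alpha = 0.4) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)", call. = FALSE)
  if (any(cf < 1)) stop("cf must be >= 1 (fragment absent from corpus)",
                        call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (c_avg <= 0) stop("c_avg must be positive", call. = FALSE)
  if (any(ff < 0) || any(compound_size < 0))
    stop("ff and compound_size must be non-negative", call. = FALSE)
  if (any(cf > m)) stop("cf cannot exceed m", call. = FALSE)
  tf <- ff / (ff + 0.5 + 1.5 * compound_size / c_avg)
  idf <- log((m + 0.5) / cf) / log(m + 1.0)
  alpha + (1 - alpha) * tf * idf
}

#' Combine fragment beliefs at the reference node
#'
#' `belief_sum()` is the SUM operator: the arithmetic mean of the beliefs
#' of the query's `n` unique fragments. `belief_wsum()` is its weighted
#' counterpart used by the fragment-reweighting model: a weighted mean
#' `sum(w * p) / sum(w)` that reduces to `belief_sum()` when all weights
#' are equal.
#'
#' @param p non-empty numeric vector of fragment beliefs.
#' @return combined belief score.
#' @export
belief_sum <- function(p) {
  if (length(p) == 0L) stop("belief list is empty", call. = FALSE)
  mean(p)
}

#' @rdname belief_sum
#' @param w positive weights, parallel to `p`, with `sum(w) > 0`.
#' @export
belief_wsum <- function(p, w) {
  if (length(p) == 0L) stop("belief list is empty", call. = FALSE)
  if (length(p) != length(w)) stop("p and w must have equal length",
                                   call. = FALSE)
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative with a positive sum",
                                      call. = FALSE)
  sum(w * p) / sum(w)
}

#' Reference sets for multi-reference fragment reweighting
#'
#' Collects a group of active reference structures and the per-fragment
#' frequency `F_fi` across the set, from which reweighting factors are
#' derived. Two readings of "frequency" are supported:
#' * `summed-counts` (default): `F_fi` is the summed occurrence count of
#'   fragment `i` over all references;
#' * `reference-count`: `F_fi` is the number of references containing
#'   fragment `i` (a document-frequency reading).
#'
#' @param queries non-empty list of [count_fp()] reference fingerprints of
#'   equal width (each non-empty).
#' @param frequency_mode `"summed-counts"` or `"reference-count"`.
#' @return an object of class `reference_set` with fields `queries`,
#'   `idx` (union of fragments), `freq` (`F_fi`), `max_freq` and
#'   `frequency_mode`.
#' @export
reference_set <- function(queries,
                          frequency_mode = c("summed-counts",
                                             "reference-count")) {
  frequency_mode <- match.arg(frequency_mode)
  if (!is.list(queries) || length(queries) == 0L)
    stop("reference set is empty", call. = FALSE)
  for (q in queries) {
    if (!inherits(q, "count_fp")) stop("queries must be count_fp objects",
                                       call. = FALSE)
    if (length(q$idx) == 0L) stop("reference fingerprints must be non-empty",
                                  call. = FALSE)
    if (q$width != queries[[1L]]$width)
      stop("reference fingerprint widths differ", call. = FALSE)
  }
  idx <- unlist(lapply(queries, `[[`, "idx"), use.names = FALSE)
  val <- if (frequency_mode == "summed-counts")
    unlist(lapply(queries, `[[`, "count"), use.names = FALSE)
  else rep(1, length(idx))
  agg <- rowsum(val, group = idx)
  structure(list(queries = queries,
                 idx = as.integer(rownames(agg)),
                 freq = as.numeric(agg),
                 max_freq = max(agg),
                 frequency_mode = frequency_mode,
                 width = queries[[1L]]$width),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d reference(s), %d fragment(s), maxF=%g (%s)\n",
              length(x$queries), length(x$idx), x$max_freq,
              x$frequency_mode))
  invisible(x)
}

#' Fragment reweighting factors from a reference set
#'
#' For every fragment of the reference-set union, the reweighting factor
#' is its frequency relative to the maximum: `rwf_i = F_fi / maxF`. Values
#' lie in `(0, 1]`; fragments occurring most frequently across the active
#' references get factor 1, rarer ones are proportionally penalized.
#'
#' @param refset a [reference_set()].
#' @return an object of class `reweight_factors` with fields `idx` and
#'   `rwf`.
#' @export
reweight_factors <- function(refset) {
  stopifnot(inherits(refset, "reference_set"))
  if (length(refset$idx) == 0L || refset$max_freq <= 0)
    stop("reference set has no fragments", call. = FALSE)
  structure(list(idx = refset$idx, rwf = refset$freq / refset$max_freq,
                 width = refset$width),
            class = "reweight_factors")
}

#' Assign new query-fragment weights from reweighting factors
#'
#' Each fragment of the query receives the new weight
#' `nw_i = w_i + rwf_i`, where `w_i` is the fragment's original frequency
#' in the query; fragments absent from the factor table keep their
#' original weight (`rwf` treated as 0).
#'
#' @param query a [count_fp()] reference structure (the single query).
#' @param factors a [reweight_factors()] object.
#' @return an object of class `reweighted_query` with fields `idx` and
#'   `new_weights`.
#' @export
apply_reweighting <- function(query, factors) {
  stopifnot(inherits(query, "count_fp"), inherits(factors, "reweight_factors"))
  if (length(query$idx) == 0L) stop("query fingerprint is empty",
                                    call. = FALSE)
  pos <- match(query$idx, factors$idx)
  add <- ifelse(is.na(pos), 0, factors$rwf[pos])
  structure(list(idx = query$idx, new_weights = query$count + add,
                 width = query$width),
            class = "reweighted_query")
}

#' Score a database against a reference structure
#'
#' Computes an activity score for every compound in the database under one
#' of the three models:
#' * `"tan"`: continuous Tanimoto between the query fingerprint and each
#'   compound fingerprint.
#' * `"bin"`: Bayesian inference network; each compound's score is the
#'   SUM-combined Okapi belief of the query's unique fragments, with the
#'   within-compound frequency read from that compound.
#' * `"binrf"`: as `"bin"`, but beliefs are combined by a normalized
#'   weighted sum with weights `nw_i` obtained by reweighting the query's
#'   fragments against the set of active references (`refset`).
#'
#' Query fragments absent from the whole collection (`cf = 0`) carry no
#' retrieval information and are dropped before belief computation.
#'
#' @param dataset an [fp_dataset()].
#' @param stats matching [corpus_stats()].
#' @param query a [count_fp()] (or a molecule id present in `dataset`).
#' @param model `"tan"`, `"bin"` or `"binrf"`.
#' @param refset a [reference_set()]; required for `"binrf"`, ignored
#'   otherwise.
#' @param alpha Okapi baseline belief, default 0.4.
#' @return named numeric vector of scores, one per database compound, in
#'   dataset order.
#' @export
score_database <- function(dataset, stats, query,
                           model = c("tan", "bin", "binrf"),
                           refset = NULL, alpha = 0.4) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "fp_dataset"), inherits(stats, "corpus_stats"))
  if (is.character(query)) query <- get_fingerprint(dataset, query)
  stopifnot(inherits(query, "count_fp"))
  if (query$width != dataset$width)
    stop("query width does not match dataset width", call. = FALSE)
  if (length(query$idx) == 0L) stop("query fingerprint is empty",
                                    call. = FALSE)
  scores <- switch(model,
    tan = score_tan(dataset, query),
    bin = score_bin(dataset, stats, query, alpha, weights = NULL),
    binrf = {
      if (is.null(refset))
        stop("model 'binrf' requires a reference set", call. = FALSE)
      stopifnot(inherits(refset, "reference_set"))
      rq <- apply_reweighting(query, reweight_factors(refset))
      score_bin(dataset, stats, query, alpha, weights = rq$new_weights)
    })
  names(scores) <- dataset$ids
  scores
}

score_tan <- function(dataset, query) {
  q <- numeric(dataset$width)
  q[query$idx + 1L] <- query$count
  dot <- as.numeric(dataset$mat %*% q)
  denom <- Matrix::rowSums(dataset$mat^2) + sum(query$count^2) - dot
  as.numeric(dot / denom)  # denom > 0: query is non-empty
}

# Shared BIN/BINRF kernel. With weights = NULL the SUM operator is used
# (plain BIN); otherwise the normalized weighted sum with the given
# per-query-fragment weights (BINRF). Exploits sparsity: a compound with
# ff = 0 for a fragment contributes exactly alpha for it, so only stored
# counts need visiting.
score_bin <- function(dataset, stats, query, alpha, weights = NULL) {
  if (!is.null(weights) && length(weights) != length(query$idx))
    stop("weights must parallel the query fragments", call. = FALSE)
  cf <- stats$cf[query$idx + 1L]
  keep <- cf > 0
  if (!any(keep))
    stop("no query fragment occurs in the collection", call. = FALSE)
  cols <- query$idx[keep] + 1L
  cf <- cf[keep]
  w <- if (is.null(weights)) rep(1, length(cols)) else weights[keep]
  m <- stats$m
  idf <- log((m + 0.5) / cf) / log(m + 1.0)
  k_norm <- 0.5 + 1.5 * stats$sizes / stats$c_avg
  sub <- as(dataset$mat[, cols, drop = FALSE], "TsparseMatrix")
  contrib <- numeric(length(dataset$ids))
  if (length(sub@x)) {
    term <- sub@x / (sub@x + k_norm[sub@i + 1L]) * (idf * w)[sub@j + 1L]
    agg <- rowsum(term, group = sub@i)
    contrib[as.integer(rownames(agg)) + 1L] <- agg
  }
  alpha + (1 - alpha) * contrib / sum(w)
}

#' Virtual-screening model objects
#'
#' A convenience modelling interface over [score_database()]: `vs_model()`
#' "fits" the model by computing the collection statistics once, and
#' `predict()` scores any query (a molecule id or a [count_fp()]) against
#' the whole database.
#'
#' @param dataset an [fp_dataset()].
#' @param model `"tan"`, `"bin"` or `"binrf"`.
#' @param alpha Okapi baseline belief in `[0, 1)`.
#' @param size_mode compound-size convention, see [corpus_stats()].
#' @param frequency_mode reference-set frequency convention, see
#'   [reference_set()].
#' @return an object of class `vs_model`.
#' @examples
#' fps <- list(count_fp(0:2, c(1, 2, 1), 16), count_fp(1:3, c(2, 1, 1), 16))
#' d <- fp_dataset(fps, c("A", "B"))
#' m <- vs_model(d, "bin")
#' predict(m, "A")
#' @export
vs_model <- function(dataset, model = c("tan", "bin", "binrf"), alpha = 0.4,
                     size_mode = "total-count",
                     frequency_mode = "summed-counts") {
  model <- match.arg(model)
  stats <- corpus_stats(dataset, size_mode = size_mode)
  structure(list(dataset = dataset, stats = stats, model = model,
                 alpha = alpha, frequency_mode = frequency_mode),
            class = "vs_model")
}

#' @export
print.vs_model <- function(x, ...) {
  cat(sprintf("<vs_model> %s over %d compound(s) (width %d, c_avg %.2f, alpha %g)\n",
              toupper(x$model), x$stats$m, x$dataset$width, x$stats$c_avg,
              x$alpha))
  invisible(x)
}

#' @export
summary.vs_model <- function(object, ...) {
  s <- object$stats
  res <- list(model = toupper(object$model), m = s$m, width = s$width,
              fragments_seen = sum(s$cf > 0), c_avg = s$c_avg,
              size_mode = s$size_mode, alpha = object$alpha)
  class(res) <- "summary.vs_model"
  res
}

#' @export
print.summary.vs_model <- function(x, ...) {
  cat(sprintf("Virtual-screening model: %s\n", x$model))
  cat(sprintf("  compounds (m):        %d\n", x$m))
  cat(sprintf("  fingerprint width:    %d\n", x$width))
  cat(sprintf("  fragments observed:   %d\n", x$fragments_seen))
  cat(sprintf("  mean compound size:   %.4f (%s)\n", x$c_avg, x$size_mode))
  cat(sprintf("  alpha:                %g\n", x$alpha))
  invisible(x)
}

#' @rdname vs_model
#' @param object a `vs_model`.
#' @param query molecule id or [count_fp()].
#' @param references for `"binrf"`: a [reference_set()], or a character
#'   vector of molecule ids from which one is built.
#' @param type `"score"` for the named score vector, `"rank"` for the
#'   ranked table of [rank_scores()].
#' @param ... unused.
#' @export
predict.vs_model <- function(object, query, references = NULL,
                             type = c("score", "rank"), ...) {
  type <- match.arg(type)
  refset <- references
  if (is.character(references))
    refset <- reference_set(lapply(references, get_fingerprint,
                                   dataset = object$dataset),
                            frequency_mode = object$frequency_mode)
  scores <- score_database(object$dataset, object$stats, query,
                           model = object$model, refset = refset,
                           alpha = object$alpha)
  if (type == "score") scores else rank_scores(scores)
}
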