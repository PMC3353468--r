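#' Reproducibly select reference structures from an activity class
#'
#' Samples `n` members without replacement. The members are sorted before
#' sampling, so the selection depends only on the set of ids, `n` and the
#' seed — never on input order.
#'
#' @param members character vector of class member ids.
#' @param n number of references to draw.
#' @param seed integer seed.
#' @return character vector of `n` molecule ids.
#' @export
select_references <- function(members, n, seed) {
  members <- sort(unique(as.character(members)))
  if (n > length(members))
    stop(sprintf("cannot select %d references from a class of %d", n,
                 length(members)), call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  with_seed(seed, sample(members, n))
}

#' Benchmark configuration
#'
#' Bundles every tunable of the simulated-screening protocol: the number
#' of randomly selected reference structures per class (10, averaged), the
#' recall cutoffs (top 1% and 5%), the models compared, and the model
#' options.
#'
#' @param seed master seed governing reference selection.
#' @param n_references references drawn per activity class, default 10.
#' @param fractions recall cutoffs, default `c(0.01, 0.05)`.
#' @param models subset of `c("tan", "bin", "binrf")`.
#' @param alpha Okapi baseline belief, default 0.4.
#' @param size_mode compound-size convention, see [corpus_stats()].
#' @param frequency_mode reference-set frequency convention, see
#'   [reference_set()].
#' @param rounding cutoff rounding, see [top_fraction_count()].
#' @param exclude_references drop the selected references from the ranked
#'   database and the actives when scoring (default `FALSE`: references
#'   stay in the database and count as actives).
#' @param near_tolerance relative tolerance for the "near-best" display
#'   mark, see [mark_cells()].
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(seed, n_references = 10L,
                             fractions = c(0.01, 0.05),
                             models = c("tan", "bin", "binrf"),
                             alpha = 0.4, size_mode = "total-count",
                             frequency_mode = "summed-counts",
                             rounding = "half-up",
                             exclude_references = FALSE,
                             near_tolerance = 0.05) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  models <- match.arg(tolower(models), c("tan", "bin", "binrf"),
                      several.ok = TRUE)
  if (any(fractions <= 0) || any(fractions >= 1))
    stop("fractions must lie strictly between 0 and 1", call. = FALSE)
  if (n_references < 1L) stop("n_references must be >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_references = as.integer(n_references),
                 fractions = sort(as.numeric(fractions)), models = models,
                 alpha = alpha, size_mode = size_mode,
                 frequency_mode = frequency_mode, rounding = rounding,
                 exclude_references = isTRUE(exclude_references),
                 near_tolerance = near_tolerance),
            class = "benchmark_config")
}

#' Run the screening protocol for one activity class
#'
#' Draws `n_references` members at random, then uses each in turn as the
#' single query: TAN and BIN score the database from that query alone,
#' while BINRF additionally reweights the query's fragments against the
#' whole selected reference set. Recall of the class is computed at each
#' cutoff and averaged over the reference structures.
#'
#' @param dataset an [fp_dataset()].
#' @param stats matching [corpus_stats()].
#' @param members character vector of the class's member ids.
#' @param config a [benchmark_config()].
#' @param class_seed seed for this class's reference selection (derived
#'   from the config seed by [run_benchmark()]).
#' @return matrix of mean recall percent, rows = fractions, columns =
#'   models, with attribute `references`.
#' @export
run_activity_class <- function(dataset, stats, members, config,
                               class_seed = config$seed) {
  stopifnot(inherits(config, "benchmark_config"))
  refs <- select_references(members, config$n_references, class_seed)
  refset <- if ("binrf" %in% config$models)
    reference_set(lapply(refs, get_fingerprint, dataset = dataset),
                  frequency_mode = config$frequency_mode)
  acc <- array(0, dim = c(length(config$fractions), length(config$models)),
               dimnames = list(format_fractions(config$fractions),
                               toupper(config$models)))
  actives <- members
  for (r in refs) {
    for (mi in seq_along(config$models)) {
      model <- config$models[mi]
      scores <- score_database(dataset, stats, r, model = model,
                               refset = refset, alpha = config$alpha)
      act <- actives
      if (config$exclude_references) {
        scores <- scores[!(names(scores) %in% setdiff(refs, r))]
        act <- setdiff(actives, setdiff(refs, r))
      }
      ranked <- rank_scores(scores)
      for (fi in seq_along(config$fractions))
        acc[fi, mi] <- acc[fi, mi] +
          recall_at(ranked, act, config$fractions[fi],
                    rounding = config$rounding)$recall_percent
    }
  }
  res <- acc / length(refs)
  attr(res, "references") <- refs
  res
}

format_fractions <- function(fractions) sprintf("top%g", 100 * fractions)

#' Run the full simulated-screening benchmark
#'
#' Executes [run_activity_class()] for every activity class and assembles,
#' per cutoff, the class-by-model recall table together with its mean row,
#' the best-cell ("share cells") counts and the Kendall concordance
#' analysis in which the activity classes judge the models.
#'
#' Each class's reference selection uses a seed derived from the config
#' seed and the class id, so results are invariant to class order and to
#' which other models are configured.
#'
#' @param dataset an [fp_dataset()].
#' @param activity activity table data.frame (`molecule_id`, `class_id`)
#'   or a named list of member-id vectors.
#' @param config a [benchmark_config()].
#' @param stats optional precomputed [corpus_stats()].
#' @param progress emit per-class progress messages to standard error.
#' @return an object of class `recall_benchmark`: a list with `recall`
#'   (list per fraction of class-by-model matrices), `means`, `share`,
#'   `marks`, `kendall` (per fraction), `references` and `config`.
#' @export
run_benchmark <- function(dataset, activity, config, stats = NULL,
                          progress = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  classes <- if (is.data.frame(activity)) activity_classes(activity, dataset)
             else activity[order(names(activity))]
  if (length(classes) == 0L) stop("no activity classes", call. = FALSE)
  if (is.null(stats)) stats <- corpus_stats(dataset,
                                            size_mode = config$size_mode)
  fr_names <- format_fractions(config$fractions)
  tables <- lapply(fr_names, function(f)
    matrix(NA_real_, length(classes), length(config$models),
           dimnames = list(names(classes), toupper(config$models))))
  names(tables) <- fr_names
  refs <- vector("list", length(classes))
  names(refs) <- names(classes)
  failures <- character()
  for (ci in seq_along(classes)) {
    cid <- names(classes)[ci]
    if (progress) message(sprintf("[benchmark] class %s (%d members)", cid,
                                  length(classes[[ci]])))
    res <- tryCatch(
      run_activity_class(dataset, stats, classes[[ci]], config,
                         class_seed = derive_seed(config$seed,
                                                  paste0("refs:", cid))),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", cid, conditionMessage(res)))
      next
    }
    refs[[ci]] <- attr(res, "references")
    for (f in fr_names) tables[[f]][ci, ] <- res[f, ]
  }
  ok <- !is.na(tables[[1L]][, 1L])
  if (!any(ok))
    stop(paste(c("all activity classes failed:", failures),
               collapse = "\n  "), call. = FALSE)
  tables <- lapply(tables, function(tb) tb[ok, , drop = FALSE])
  marks <- if (length(config$models) >= 2L)
    lapply(tables, mark_cells, near_tolerance = config$near_tolerance)
  kendall <- if (length(config$models) >= 2L)
    lapply(tables, kendall_w) else NULL
  structure(list(recall = tables,
                 means = lapply(tables, colMeans),
                 share = if (!is.null(marks)) lapply(marks, attr, "share"),
                 marks = marks,
                 kendall = kendall,
                 references = refs[ok],
                 failures = failures,
                 config = config),
            class = "recall_benchmark")
}

#' @export
print.recall_benchmark <- function(x, digits = 2, ...) {
  for (f in names(x$recall)) {
    cat(sprintf("Mean recall (%%), %s of the ranked database:\n", f))
    tb <- rbind(round(x$recall[[f]], digits),
                Mean = round(x$means[[f]], digits))
    if (!is.null(x$share)) tb <- rbind(tb, `Share cells` = x$share[[f]])
    print(tb)
    if (!is.null(x$kendall)) {
      k <- x$kendall[[f]]
      cat(sprintf("Kendall W = %.3f (chi2 = %.2f, p = %.3g): %s\n\n",
                  k$W, k$chi_square, k$p_value,
                  paste(k$ordering, collapse = " > ")))
    }
  }
  if (length(x$failures))
    cat("Skipped classes:\n ", paste(x$failures, collapse = "\n  "), "\n")
  invisible(x)
}

#' Column mean of a recall table
#'
#' The statistic of the tables' penultimate row: the arithmetic mean of a
#' model's per-class recall values.
#'
#' @param column non-empty numeric vector.
#' @return arithmetic mean.
#' @export
table_mean <- function(column) {
  if (length(column) == 0L) stop("empty column", call. = FALSE)
  mean(column)
}

#' Mark best and near-best cells of a recall table
#'
#' Per activity class (row), the model with the highest recall is marked
#' `"**"` (ties: every maximal cell); any other model within
#' `near_tolerance` (relative) of the best is marked `"*"` for display.
#' The per-model count of `"**"` cells is the "share cells" statistic
#' reported under each recall table; near-best marks never enter the
#' counts.
#'
#' @param block numeric matrix, rows = activity classes, columns = models
#'   (at least 2).
#' @param near_tolerance relative near-best tolerance, default 0.05.
#' @return character matrix of marks with attribute `share` (named integer
#'   vector of best-cell counts per model).
#' @export
mark_cells <- function(block, near_tolerance = 0.05) {
  block <- as.matrix(block)
  if (nrow(block) < 1L || ncol(block) < 2L)
    stop("block must have >= 1 row and >= 2 columns", call. = FALSE)
  marks <- matrix("", nrow(block), ncol(block), dimnames = dimnames(block))
  for (i in seq_len(nrow(block))) {
    best <- max(block[i, ])
    is_best <- block[i, ] == best
    marks[i, is_best] <- "**"
    near <- !is_best & block[i, ] >= best * (1 - near_tolerance)
    marks[i, near] <- "*"
  }
  share <- colSums(marks == "**")
  storage.mode(share) <- "integer"
  attr(marks, "share") <- share
  marks
}

#' Kendall coefficient of concordance
#'
#' Measures the agreement of `m` judges ranking the same `n` objects; in
#' the benchmark the activity classes are the judges and the models the
#' objects (higher recall = higher rank = better). Ties receive average
#' ranks and the tie-corrected statistic is used:
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum T_j}}
#' where `S` is the sum of squared deviations of the objects' rank sums
#' and `T_j = sum(t^3 - t)` over the tie groups of judge `j`. Significance
#' uses the chi-square approximation `chi2 = m (n - 1) W` on `n - 1`
#' degrees of freedom.
#'
#' @param values numeric matrix, rows = judges, columns = objects (at
#'   least 2 objects); higher values are better.
#' @return an object of class `kendall_w` with fields `W`, `chi_square`,
#'   `df`, `p_value`, `mean_ranks` and `ordering` (object names, best
#'   first).
#' @export
kendall_w <- function(values) {
  values <- as.matrix(values)
  m <- nrow(values)
  n <- ncol(values)
  if (n < 2L) stop("at least 2 objects are required", call. = FALSE)
  if (m < 1L) stop("at least 1 judge is required", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("obj", seq_len(n))
  ranks <- t(apply(values, 1L, rank))
  if (m == 1L) ranks <- matrix(ranks, 1L)  # apply drops the dimension
  rank_sums <- colSums(ranks)
  s <- sum((rank_sums - m * (n + 1) / 2)^2)
  ties <- apply(ranks, 1L, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(ties)
  w <- if (denom > 0) 12 * s / denom else NA_real_
  chi2 <- m * (n - 1) * w
  p <- pchisq(chi2, df = n - 1, lower.tail = FALSE)
  mean_ranks <- rank_sums / m
  ord <- order(-mean_ranks, colnames(values))
  structure(list(W = w, chi_square = chi2, df = n - 1L, p_value = p,
                 mean_ranks = mean_ranks,
                 ordering = colnames(values)[ord], m = m, n = n),
            class = "kendall_w")
}

#' @export
print.kendall_w <- function(x, ...) {
  cat(sprintf("Kendall W = %.4f (m = %d judges, n = %d objects)\n", x$W,
              x$m, x$n))
  cat(sprintf("chi-square = %.4f on %d df, p = %.4g\n", x$chi_square, x$df,
              x$p_value))
  cat("ranking:", paste(x$ordering, collapse = " > "), "\n")
  invisible(x)
}

#' Summarize an existing recall table
#'
#' Recomputes, from a class-by-model recall matrix (for example one read
#' back from a published table or a previous run), the statistics printed
#' under it: the mean row, the best-cell marks and counts, and the Kendall
#' concordance analysis.
#'
#' @param block numeric matrix, rows = activity classes, columns = models.
#' @param near_tolerance relative near-best display tolerance.
#' @return list with `mean`, `share`, `marks` and `kendall`.
#' @export
summarize_recall_table <- function(block, near_tolerance = 0.05) {
  block <- as.matrix(block)
  marks <- mark_cells(block, near_tolerance = near_tolerance)
  list(mean = colMeans(block),
       share = attr(marks, "share"),
       marks = marks,
       kendall = if (ncol(block) >= 2L) kendall_w(block) else NULL)
}
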