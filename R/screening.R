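#' Rank a score map deterministically
#'
#' Orders compounds by decreasing score; ties are broken by ascending
#' molecule id so that a ranking is reproducible across runs, platforms and
#' input orderings.
#'
#' @param scores non-empty named numeric vector (names are molecule ids),
#'   all finite.
#' @return a data.frame of class `ranked_list` with columns `rank`,
#'   `molecule_id` and `score`.
#' @export
rank_scores <- function(scores) {
  if (length(scores) == 0L) stop("score map is empty", call. = FALSE)
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be named by molecule_id", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  o <- order(-scores, names(scores), method = "radix")
  out <- data.frame(rank = seq_along(scores),
                    molecule_id = names(scores)[o],
                    score = as.numeric(scores[o]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Number of compounds in the top fraction of a ranking
#'
#' Converts a fractional cutoff (for example 0.01 for "top 1%") into a
#' count of list positions. The default rounds half up, with a minimum of
#' one position; `"floor"` and `"ceiling"` variants are provided because
#' the convention is not standardized.
#'
#' @param n database size (positive integer).
#' @param fraction cutoff fraction, strictly between 0 and 1.
#' @param rounding `"half-up"`, `"floor"` or `"ceiling"`.
#' @return positive integer cutoff count.
#' @examples
#' top_fraction_count(102516, 0.01)  # 1025
#' @export
top_fraction_count <- function(n, fraction,
                               rounding = c("half-up", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("n must be a positive integer", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  k <- switch(rounding,
              "half-up" = floor(fraction * n + 0.5),
              "floor" = floor(fraction * n),
              "ceiling" = ceiling(fraction * n))
  as.integer(max(1, k))
}

#' Recall of an activity class in the top fraction of a ranking
#'
#' The fraction (as a percentage) of an activity class retrieved within
#' the top `fraction` of the ranked database — the enrichment measure used
#' throughout the benchmark.
#'
#' @param ranked a [rank_scores()] ranking of the whole database.
#' @param actives non-empty character vector of active molecule ids, all
#'   present in the ranking.
#' @inheritParams top_fraction_count
#' @return an object of class `recall_result` with fields `fraction`,
#'   `cutoff_count`, `retrieved_actives`, `total_actives` and
#'   `recall_percent`.
#' @export
recall_at <- function(ranked, actives, fraction,
                      rounding = c("half-up", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(ranked, "ranked_list"))
  actives <- unique(as.character(actives))
  if (length(actives) == 0L) stop("actives set is empty", call. = FALSE)
  missing <- setdiff(actives, ranked$molecule_id)
  if (length(missing))
    stop(sprintf("active id absent from ranking: %s", missing[1L]),
         call. = FALSE)
  k <- top_fraction_count(nrow(ranked), fraction, rounding)
  retrieved <- sum(ranked$molecule_id[seq_len(k)] %in% actives)
  structure(list(fraction = fraction, cutoff_count = k,
                 retrieved_actives = retrieved,
                 total_actives = length(actives),
                 recall_percent = 100 * retrieved / length(actives)),
            class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("recall@%g%%: %d/%d actives in top %d (%.2f%%)\n",
              100 * x$fraction, x$retrieved_actives, x$total_actives,
              x$cutoff_count, x$recall_percent))
  invisible(x)
}

#' Write a ranked list as tab-separated text
#'
#' Rows are `rank\tmolecule_id\tscore` with 6-decimal fixed score
#' formatting, so reruns are byte-identical.
#'
#' @param ranked a [rank_scores()] result.
#' @param path file to write.
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  lines <- c("rank\tmolecule_id\tscore",
             sprintf("%d\t%s\t%.6f", ranked$rank, ranked$molecule_id,
                     ranked$score))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
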