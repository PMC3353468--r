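# Small in-code fixtures shared across test files.

# A fingerprint from a compact spec: fp(c(`1` = 2, `7` = 1)) means
# fragment 1 with count 2 and fragment 7 with count 1.
fp <- function(x = numeric(), width = 16L) {
  count_fp(as.integer(names(x)), as.numeric(x), width = width)
}

# Five-molecule toy database used by model and screening tests.
tiny_dataset <- function(width = 16L) {
  fp_dataset(list(
    fp(c(`0` = 1, `1` = 2, `2` = 1), width),
    fp(c(`1` = 2, `2` = 1, `3` = 1), width),
    fp(c(`0` = 1, `1` = 2, `2` = 1), width),   # exact copy of M1
    fp(c(`8` = 3, `9` = 1), width),
    fp(c(`2` = 2, `8` = 1, `10` = 1), width)),
    c("M1", "M2", "M3", "M4", "M5"))
}

# Per-compound BIN/BINRF score computed the slow, literal way: one
# okapi_belief() call per query fragment, combined by belief_sum() or
# belief_wsum(). Independent of the vectorized score_database() path.
naive_bin_scores <- function(dataset, stats, query, alpha = 0.4,
                             weights = NULL) {
  keep <- stats$cf[query$idx + 1L] > 0
  idx <- query$idx[keep]
  w <- if (is.null(weights)) NULL else weights[keep]
  out <- vapply(seq_along(dataset$ids), function(j) {
    row <- dataset$mat[j, ]
    p <- vapply(idx, function(i)
      okapi_belief(row[i + 1L], stats$sizes[[j]], stats$cf[i + 1L],
                   stats$m, stats$c_avg, alpha), numeric(1))
    if (is.null(w)) belief_sum(p) else belief_wsum(p, w)
  }, numeric(1))
  names(out) <- dataset$ids
  out
}

synth_cfg_small <- function(...) {
  args <- utils::modifyList(list(width = 256L, n_background = 60L,
                                 fragments_per_molecule = 20),
                            list(...))
  do.call(synth_config, args)
}
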