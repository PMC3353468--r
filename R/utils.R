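#' @keywords internal
"_PACKAGE"

#' @importFrom methods as new
#' @importFrom stats pchisq qgamma rgamma rgeom rpois runif median
#' @importFrom utils read.csv write.csv packageVersion head
NULL

# Mersenne prime used for all modular hashing of seeds/checksums.
.MOD31 <- 2147483647

#' Derive an independent seed from a master seed and a stream label
#'
#' Every source of randomness in the package draws its seed from a single
#' master seed plus a textual stream label, so that (for example) adding a
#' model to a benchmark run does not shift the reference structures another
#' model sees.
#'
#' @param seed master seed (integer-like scalar).
#' @param label character scalar naming the stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  h <- as.numeric(seed) %% .MOD31
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% .MOD31
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# match.arg with friendlier error text for user-facing option strings.
match_option <- function(value, choices, what) {
  if (!is.character(value) || length(value) != 1L || !(value %in% choices))
    stop(sprintf("invalid %s: %s (expected one of: %s)", what,
                 deparse(substitute(value)), paste(choices, collapse = ", ")),
         call. = FALSE)
  value
}
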