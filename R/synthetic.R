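#' Synthetic benchmark configuration
#'
#' Parameters of the MDDR-like synthetic fingerprint generator. Molecules
#' draw a number of distinct fragments from a Poisson distribution
#' truncated below at `min_fragments`, fragment indices uniformly over the
#' folded index space, and per-fragment occurrence counts from a geometric
#' distribution shifted to start at 1 (`count_decay` is the geometric
#' success probability; the mean count is `1 + (1 - count_decay) /
#' count_decay`).
#'
#' @param width fingerprint width, default 1024.
#' @param n_background number of background (inactive) molecules, default
#'   5000.
#' @param fragments_per_molecule Poisson mean of the distinct-fragment
#'   count, default 60.
#' @param min_fragments lower truncation of the fragment count, default 10.
#' @param count_decay geometric success probability of the per-fragment
#'   count distribution, default 0.8 (mean count 1.25; folded circular
#'   count fingerprints of drug-like molecules are dominated by counts of
#'   1 and 2).
#' @param retention_shape shape of the Gamma(shape, rate = shape)
#'   distribution (mean 1) of the per-fragment retention exponents that
#'   split an activity class's prototype into conserved core fragments and
#'   variable peripheral ones; smaller values give a stronger
#'   core/periphery contrast. Default 0.5. See [generate_class()].
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(width = 1024L, n_background = 5000L,
                         fragments_per_molecule = 60,
                         min_fragments = 10L, count_decay = 0.8,
                         retention_shape = 0.5) {
  stopifnot(width >= 1L, n_background >= 0L, fragments_per_molecule > 0,
            min_fragments >= 1L, count_decay > 0, count_decay < 1,
            retention_shape > 0)
  structure(list(width = as.integer(width),
                 n_background = as.integer(n_background),
                 fragments_per_molecule = fragments_per_molecule,
                 min_fragments = as.integer(min_fragments),
                 count_decay = count_decay,
                 retention_shape = retention_shape),
            class = "synth_config")
}

# Draw one molecule's distinct-fragment count / indices / counts.
draw_molecules <- function(n, config) {
  nf <- pmax(config$min_fragments,
             rpois(n, config$fragments_per_molecule))
  idx <- lapply(nf, function(k) sample.int(config$width, k) - 1L)
  cnt <- lapply(nf, function(k) 1 + rgeom(k, config$count_decay))
  list(nf = nf, idx = idx, cnt = cnt)
}

#' Generate a background fingerprint database
#'
#' Background molecules emulate the bulk of a screening database: they are
#' unrelated to every activity class, with fragments placed uniformly at
#' random. Reproducible for a given seed.
#'
#' @param n number of molecules (may be 0).
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param id_prefix prefix of the generated molecule ids.
#' @return an [fp_dataset()].
#' @export
generate_background <- function(n, config, seed, id_prefix = "BG") {
  stopifnot(inherits(config, "synth_config"), n >= 0)
  ids <- if (n > 0) sprintf("%s%06d", id_prefix, seq_len(n)) else character()
  if (n == 0L)
    return(new_fp_dataset(sparse_counts(integer(), integer(), numeric(),
                                        dims = c(0L, config$width)),
                          ids, config$width))
  d <- with_seed(seed, draw_molecules(n, config))
  mat <- sparse_counts(i = rep.int(seq_len(n), d$nf),
                       j = unlist(d$idx, use.names = FALSE) + 1L,
                       x = unlist(d$cnt, use.names = FALSE),
                       dims = c(n, config$width))
  new_fp_dataset(mat, ids, config$width)
}

#' Generate one activity class around a prototype molecule
#'
#' A prototype molecule is drawn as in [generate_background()]; every class
#' member keeps each prototype fragment independently and replaces each
#' deletion with a fresh uniformly placed fragment, so molecule size in
#' fragments is preserved in expectation.
#'
#' Retention is not uniform across the prototype: fragment `i` is kept
#' with probability `(1 - q)^e_i`, where the exponents `e_i` are drawn
#' once per class from a mean-1 Gamma distribution
#' (`retention_shape`, see [synth_config()]). Small exponents give
#' conserved "core" fragments present in almost every member (the
#' scaffold/pharmacophore of a real activity class); large exponents give
#' peripheral decoration that individual members rarely share. `q = 0`
#' yields identical members (mean pairwise similarity 1); `q = 1` yields
#' members as unrelated as background molecules.
#'
#' For a fixed seed the kept fragment sets shrink monotonically as `q`
#' grows (the retention uniforms and the replacement draws are fixed per
#' member/slot), which makes diversity calibration by bisection exact and
#' deterministic.
#'
#' @param class_id class identifier; member ids are
#'   `<class_id>_<k>`.
#' @param size number of members.
#' @param q perturbation level in `[0, 1]`.
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return an [fp_dataset()] of the class members.
#' @export
generate_class <- function(class_id, size, q, config, seed) {
  stopifnot(inherits(config, "synth_config"), size >= 1, q >= 0, q <= 1)
  draws <- with_seed(seed, {
    proto_nf <- max(config$min_fragments,
                    rpois(1L, config$fragments_per_molecule))
    list(proto_idx = sample.int(config$width, proto_nf) - 1L,
         proto_cnt = 1 + rgeom(proto_nf, config$count_decay),
         # stratified Gamma quantiles: every prototype carries the same
         # retention spectrum (assigned to fragments in random order), so
         # class diversity at a given q is stable across prototypes
         expo = sample(qgamma(stats::ppoints(proto_nf),
                              shape = config$retention_shape,
                              rate = config$retention_shape)),
         u = matrix(runif(size * proto_nf), nrow = size),
         rep_idx = matrix(sample.int(config$width, size * proto_nf,
                                     replace = TRUE) - 1L, nrow = size),
         rep_cnt = matrix(1 + rgeom(size * proto_nf, config$count_decay),
                          nrow = size))
  })
  p_keep <- (1 - q)^draws$expo
  fps <- vector("list", size)
  for (k in seq_len(size)) {
    keep <- draws$u[k, ] < p_keep
    idx <- c(draws$proto_idx[keep], draws$rep_idx[k, !keep])
    cnt <- c(draws$proto_cnt[keep], draws$rep_cnt[k, !keep])
    agg <- rowsum(cnt, group = idx)  # replacement may collide with a kept bin
    fps[[k]] <- count_fp(as.integer(rownames(agg)), as.numeric(agg),
                         width = config$width)
  }
  fp_dataset(fps, sprintf("%s_%04d", class_id, seq_len(size)),
             width = config$width)
}

#' Calibrate the perturbation probability to a target class diversity
#'
#' Finds, by bisection, the perturbation probability `q` at which the mean
#' pairwise binary Tanimoto similarity of a generated class matches
#' `target_diversity`. The estimate averages a few probe classes of fixed
#' size generated under seeds derived from `seed`, with common random
#' numbers across bisection steps, so the search is deterministic and the
#' estimated diversity is monotone in `q`.
#'
#' Targets below the background similarity floor (unrelated molecules
#' still share fragments by chance) are unattainable; the nearest
#' achievable value is returned with a warning.
#'
#' @param target_diversity target mean pairwise similarity in `(0, 1]`.
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param tolerance acceptable |achieved - target|, default 0.02.
#' @param probe_size members per probe class, default 50.
#' @param n_probes probe classes averaged per estimate, default 3.
#' @return the calibrated `q`, with attribute `achieved` (the estimated
#'   diversity at `q`).
#' @export
calibrate_perturbation <- function(target_diversity, config, seed,
                                   tolerance = 0.02, probe_size = 50L,
                                   n_probes = 3L) {
  stopifnot(inherits(config, "synth_config"))
  if (target_diversity <= 0 || target_diversity > 1)
    stop("target_diversity must lie in (0, 1]", call. = FALSE)
  probe_seeds <- vapply(seq_len(n_probes), function(i)
    derive_seed(seed, paste0("probe:", i)), integer(1))
  estimate <- function(q) {
    sims <- vapply(probe_seeds, function(s) {
      cls <- generate_class("PROBE", probe_size, q, config, s)
      b <- cls$mat
      b@x[] <- 1
      mean_pairwise_tanimoto(b)
    }, numeric(1))
    mean(sims)
  }
  if (estimate(0) <= target_diversity + tolerance)
    return(structure(0, achieved = estimate(0)))
  floor_div <- estimate(1)
  if (floor_div > target_diversity + tolerance) {
    warning(sprintf(paste0("target diversity %.3f is below the background",
                           " floor; nearest achievable is %.3f"),
                    target_diversity, floor_div), call. = FALSE)
    return(structure(1, achieved = floor_div))
  }
  lo <- 0
  hi <- 1
  q <- 0.5
  for (iter in seq_len(40L)) {
    q <- (lo + hi) / 2
    est <- estimate(q)
    if (abs(est - target_diversity) <= tolerance / 2) break
    if (est > target_diversity) lo <- q else hi <- q
  }
  structure(q, achieved = estimate(q))
}

#' Published MDDR benchmark activity-class structure
#'
#' Returns the activity-class table of one of the three published MDDR
#' screening benchmarks: DS1 (11 classes of mixed diversity), DS2 (10
#' structurally homogeneous classes) or DS3 (10 structurally heterogeneous
#' classes), with the published class sizes and mean pairwise similarities.
#'
#' @param name `"ds1"`, `"ds2"` or `"ds3"`.
#' @return data.frame with columns `class_id`, `activity_class`, `size`
#'   and `diversity`.
#' @export
mddr_classes <- function(name = c("ds1", "ds2", "ds3")) {
  name <- match.arg(tolower(name), c("ds1", "ds2", "ds3"))
  path <- system.file("extdata", sprintf("mddr_%s_classes.tsv", name),
                      package = "binrf", mustWork = TRUE)
  df <- read.delim(path, colClasses = c("character", "character",
                                        "integer", "numeric"))
  names(df) <- c("class_id", "activity_class", "size", "diversity")
  df
}

#' Published MDDR benchmark recall tables
#'
#' Returns the published per-class recall values (percent of the activity
#' class retrieved in the top 1% and 5% of the ranked database, averaged
#' over ten reference structures) for the three screening models on one of
#' the MDDR benchmarks. These are the printed result tables shipped with
#' the package so that their summary statistics (mean rows, best-cell
#' counts, Kendall concordance) can be recomputed exactly.
#'
#' @inheritParams mddr_classes
#' @return list of two class-by-model matrices, `top1` and `top5`, with
#'   columns `TAN`, `BIN`, `BINRF`.
#' @export
mddr_recall <- function(name = c("ds1", "ds2", "ds3")) {
  name <- match.arg(tolower(name), c("ds1", "ds2", "ds3"))
  path <- system.file("extdata", sprintf("mddr_%s_recall.tsv", name),
                      package = "binrf", mustWork = TRUE)
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  take <- function(suffix) {
    m <- as.matrix(df[, paste0(c("TAN", "BIN", "BINRF"), suffix)])
    storage.mode(m) <- "numeric"
    dimnames(m) <- list(df$class_id, c("TAN", "BIN", "BINRF"))
    m
  }
  list(top1 = take("_1"), top5 = take("_5"))
}

#' Generate a complete synthetic screening benchmark
#'
#' Builds a background database plus one generated activity class per
#' spec, each calibrated to its target diversity, and the matching
#' activity membership table. The presets `"ds1-like"`, `"ds2-like"` and
#' `"ds3-like"` mirror the class counts, relative sizes and diversity
#' columns of the published MDDR benchmarks at one tenth scale (class
#' sizes divided by 10 with a floor of 11 members; 5000 background
#' molecules).
#'
#' @param class_specs data.frame with columns `class_id`, `size` and
#'   `diversity` (target mean pairwise similarity), or a preset name
#'   `"ds1-like"` / `"ds2-like"` / `"ds3-like"`.
#' @param seed integer master seed; generation and calibration use derived
#'   streams.
#' @param config a [synth_config()].
#' @param scale divisor applied to preset class sizes, default 10.
#' @return list with `dataset` (an [fp_dataset()]), `activity`
#'   (data.frame `molecule_id`, `class_id`), `classes` (the resolved
#'   specs with calibrated `q` and achieved diversity) and `config`.
#' @export
generate_benchmark <- function(class_specs, seed, config = synth_config(),
                               scale = 10) {
  stopifnot(inherits(config, "synth_config"))
  if (is.character(class_specs) && length(class_specs) == 1L) {
    preset <- match.arg(tolower(class_specs),
                        c("ds1-like", "ds2-like", "ds3-like"))
    cls <- mddr_classes(sub("-like$", "", preset))
    class_specs <- data.frame(class_id = cls$class_id,
                              size = pmax(11L, as.integer(ceiling(cls$size / scale))),
                              diversity = cls$diversity,
                              stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(class_specs),
            all(c("class_id", "size", "diversity") %in% names(class_specs)))
  check_ids(class_specs$class_id)
  background <- generate_background(config$n_background, config,
                                    derive_seed(seed, "background"))
  parts <- list(background)
  activity <- list()
  qs <- numeric(nrow(class_specs))
  achieved <- numeric(nrow(class_specs))
  for (i in seq_len(nrow(class_specs))) {
    cid <- class_specs$class_id[i]
    q <- calibrate_perturbation(class_specs$diversity[i], config,
                                derive_seed(seed, paste0("calib:", cid)))
    qs[i] <- as.numeric(q)
    achieved[i] <- attr(q, "achieved")
    cls <- generate_class(cid, class_specs$size[i], qs[i], config,
                          derive_seed(seed, paste0("class:", cid)))
    parts[[length(parts) + 1L]] <- cls
    activity[[length(activity) + 1L]] <-
      data.frame(molecule_id = cls$ids, class_id = cid,
                 stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, lapply(parts, `[[`, "mat"))
  ids <- unlist(lapply(parts, `[[`, "ids"), use.names = FALSE)
  check_ids(ids)
  specs <- class_specs
  specs$q <- qs
  specs$achieved_diversity <- achieved
  list(dataset = new_fp_dataset(mat, ids, config$width),
       activity = do.call(rbind, activity),
       classes = specs,
       config = config,
       seed = as.integer(seed))
}
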