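#' Write benchmark reports
#'
#' Renders a [run_benchmark()] result to a directory: one tab-separated
#' recall table per cutoff (class rows plus `Mean` and `Share_cells`
#' rows), a Kendall summary table, a human-readable text report and a JSON
#' run manifest. All formatting is fixed-width, so a rerun with the same
#' configuration and seed writes byte-identical files.
#'
#' @param result a `recall_benchmark` from [run_benchmark()].
#' @param dir output directory (created if missing).
#' @param name dataset label used in file names, default `"dataset"`.
#' @param inputs optional named character vector of input file paths to
#'   checksum into the manifest.
#' @return (invisibly) the character vector of files written.
#' @export
render_report <- function(result, dir, name = "dataset", inputs = NULL) {
  stopifnot(inherits(result, "recall_benchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (f in names(result$recall)) {
    path <- file.path(dir, sprintf("recall_%s_%s.tsv", name, f))
    write_recall_tsv(result$recall[[f]], result$means[[f]],
                     result$share[[f]] %||% integer(ncol(result$recall[[f]])),
                     path)
    files <- c(files, path)
  }
  kpath <- file.path(dir, "summary_kendall.tsv")
  klines <- "fraction\tW\tchi_square\tp_value\tranking"
  if (!is.null(result$kendall))
    for (f in names(result$kendall)) {
      k <- result$kendall[[f]]
      klines <- c(klines, sprintf("%s\t%.6f\t%.6f\t%.6g\t%s", f, k$W,
                                  k$chi_square, k$p_value,
                                  paste(k$ordering, collapse = " > ")))
    }
  writeLines(klines, kpath, useBytes = TRUE)
  files <- c(files, kpath)

  rpath <- file.path(dir, "report.txt")
  con <- textConnection("report_buf", "w", local = TRUE)
  sink(con)
  cat(sprintf("Simulated screening benchmark: %s\n", name))
  cat(sprintf("seed=%d  n_references=%d  models=%s  alpha=%g\n",
              result$config$seed, result$config$n_references,
              paste(result$config$models, collapse = ","),
              result$config$alpha))
  cat(sprintf("size_mode=%s  frequency_mode=%s  rounding=%s\n\n",
              result$config$size_mode, result$config$frequency_mode,
              result$config$rounding))
  print(result)
  sink()
  close(con)
  writeLines(report_buf, rpath, useBytes = TRUE)
  files <- c(files, rpath)

  mpath <- file.path(dir, "manifest.json")
  manifest <- run_manifest(result$config, name = name, inputs = inputs,
                           outputs = basename(c(files, mpath)))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, mpath)
  invisible(files)
}

write_recall_tsv <- function(block, means, share, path) {
  models <- colnames(block)
  lines <- c(paste(c("class_id", models), collapse = "\t"),
             vapply(seq_len(nrow(block)), function(i)
               paste(c(rownames(block)[i], sprintf("%.4f", block[i, ])),
                     collapse = "\t"), character(1)),
             paste(c("Mean", sprintf("%.4f", means)), collapse = "\t"),
             paste(c("Share_cells", sprintf("%d", share)), collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read back a recall table written by [render_report()]
#'
#' Strips the `Mean` and `Share_cells` summary rows and returns the
#' class-by-model matrix, ready for [summarize_recall_table()].
#'
#' @param path a `recall_*.tsv` file (or any TSV with a `class_id` first
#'   column and one numeric column per model).
#' @return numeric matrix, rows named by class id, columns by model.
#' @export
read_recall_table <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L)
    stop(sprintf("%s: expected class_id plus model columns", path),
         call. = FALSE)
  df <- df[!(df[[1L]] %in% c("Mean", "Share_cells")), , drop = FALSE]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop(sprintf("%s: non-numeric recall cell", path),
                     call. = FALSE)
  rownames(m) <- df[[1L]]
  m
}

# Manifest describing a run: configuration snapshot, seed, input
# checksums and output list. Sufficient to reproduce outputs bit-for-bit.
run_manifest <- function(config, name, inputs = NULL, outputs = character()) {
  checksums <- NULL
  if (!is.null(inputs))
    checksums <- lapply(inputs, function(p)
      if (file.exists(p)) file_checksum(p) else NA_character_)
  list(tool = "binrf", version = as.character(packageVersion("binrf")),
       name = name, seed = config$seed,
       config = unclass(config), input_checksums = checksums,
       outputs = as.list(outputs))
}

file_checksum <- function(path) {
  h <- 0
  for (line in readLines(path, warn = FALSE))
    h <- (h * 31 + sum(utf8ToInt(line))) %% .MOD31
  sprintf("%d", as.integer(h))
}
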