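#' Build a time-course expression experiment
#'
#' `timecourse()` bundles a feature-by-sample signal matrix with its sample
#' annotation (time point in days in vitro, replicate index) and, optionally,
#' a matching matrix of detection p-values (the Illumina convention: the
#' probability that a probe's signal is indistinguishable from background).
#'
#' @param signal numeric matrix, features (probes or genes) in rows, samples
#'   in columns. Row names are feature IDs, column names sample IDs.
#' @param samples data frame with one row per column of `signal`, containing
#'   at least `sample`, `div` (time point, days in vitro) and `replicate`.
#' @param detection optional numeric matrix of detection p-values with the
#'   same dimnames as `signal`.
#' @param level `"probe"` or `"gene"`.
#' @param log2 logical; `TRUE` once the signal is on the log2 scale.
#'
#' @return An object of class `timecourse`: a list with elements `signal`,
#'   `samples` (tibble), `detection`, `level` and `log2`.
#' @export
timecourse <- function(signal, samples, detection = NULL,
                       level = c("probe", "gene"), log2 = FALSE) {
  level <- match.arg(level)
  signal <- as.matrix(signal)
  if (is.null(rownames(signal))) {
    stop("`signal` must have row names (feature IDs)")
  }
  samples <- tibble::as_tibble(samples)
  required <- c("sample", "div", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("`samples` lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) != ncol(signal)) {
    stop("`samples` rows (", nrow(samples), ") must match signal columns (",
         ncol(signal), ")")
  }
  if (is.null(colnames(signal))) colnames(signal) <- samples$sample
  if (anyDuplicated(paste(samples$div, samples$replicate))) {
    stop("every (div, replicate) pair must be unique")
  }
  if (!is.null(detection)) {
    detection <- as.matrix(detection)
    if (!identical(dim(detection), dim(signal))) {
      stop("`detection` must have the same dimensions as `signal`")
    }
    dimnames(detection) <- dimnames(signal)
  }
  structure(
    list(signal = signal, samples = samples, detection = detection,
         level = level, log2 = log2),
    class = "timecourse"
  )
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf(
    "<timecourse> %d %s feature(s) x %d sample(s); %d time point(s) x %d replicate(s); %s scale%s\n",
    nrow(x$signal), x$level, ncol(x$signal),
    dplyr::n_distinct(x$samples$div), dplyr::n_distinct(x$samples$replicate),
    if (x$log2) "log2" else "linear",
    if (is.null(x$detection)) "" else "; detection p present"
  ))
  invisible(x)
}

#' @export
dim.timecourse <- function(x) dim(x$signal)

#' Sample-level tidy view of a timecourse
#'
#' @param x a [timecourse()] object.
#' @param ... unused.
#' @return A tibble with one row per (feature, sample) pair: columns
#'   `feature`, `sample`, `div`, `replicate`, `signal` and (when present)
#'   `detection_p`.
#' @export
tidy.timecourse <- function(x, ...) {
  out <- tibble::tibble(
    feature = rep(rownames(x$signal), times = ncol(x$signal)),
    sample = rep(x$samples$sample, each = nrow(x$signal)),
    div = rep(x$samples$div, each = nrow(x$signal)),
    replicate = rep(x$samples$replicate, each = nrow(x$signal)),
    signal = as.vector(x$signal)
  )
  if (!is.null(x$detection)) out$detection_p <- as.vector(x$detection)
  out
}

#' Mean log2 fold change trajectories versus baseline
#'
#' For every feature, averages log2 signal over replicates within each time
#' point and subtracts the baseline time point, yielding the per-gene
#' trajectory used by the dynamic time warping and clustering stages.
#'
#' @param x a log2-scale [timecourse()] object.
#' @param baseline baseline time point (default 0 days in vitro).
#' @return numeric matrix, features x time points (ordered), of log2 fold
#'   changes relative to `baseline`; the baseline column is 0.
#' @export
log2fc_trajectories <- function(x, baseline = 0) {
  stopifnot(inherits(x, "timecourse"))
  if (!x$log2) stop("signal must be on the log2 scale; run preprocessing first")
  divs <- sort(unique(x$samples$div))
  if (!baseline %in% divs) stop("baseline time point ", baseline, " not present")
  means <- vapply(divs, function(d) {
    rowMeans(x$signal[, x$samples$div == d, drop = FALSE])
  }, numeric(nrow(x$signal)))
  colnames(means) <- as.character(divs)
  means - means[, as.character(baseline)]
}

# ---- tab-delimited IO ------------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_tsv <- function(m, path, id_col = "feature") {
  df <- cbind(rownames(m),
              matrix(fmt_num(m), nrow = nrow(m), ncol = ncol(m)))
  lines <- c(paste(c(id_col, colnames(m)), collapse = "\t"),
             apply(df, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Read / write signal and detection matrices
#'
#' Tab-delimited, features in rows and samples in columns, with a header row
#' and the feature ID in the first column. Values are written with 17
#' significant digits so a write/read cycle is bit-exact for doubles.
#'
#' @param x a [timecourse()] object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `write_timecourse()` returns the written paths invisibly;
#'   `read_timecourse()` returns a [timecourse()] object.
#' @export
write_timecourse <- function(x, dir, prefix = "experiment") {
  stopifnot(inherits(x, "timecourse"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(signal = file.path(dir, paste0(prefix, "_signal.tsv")),
             samples = file.path(dir, paste0(prefix, "_samples.tsv")))
  write_matrix_tsv(x$signal, paths[["signal"]])
  utils::write.table(x$samples, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(x$detection)) {
    paths[["detection"]] <- file.path(dir, paste0(prefix, "_detection.tsv"))
    write_matrix_tsv(x$detection, paths[["detection"]])
  }
  invisible(paths)
}

#' @rdname write_timecourse
#' @param level,log2 passed to [timecourse()].
#' @export
read_timecourse <- function(dir, prefix = "experiment",
                            level = "probe", log2 = FALSE) {
  signal <- read_matrix_tsv(file.path(dir, paste0(prefix, "_signal.tsv")))
  samples <- utils::read.delim(file.path(dir, paste0(prefix, "_samples.tsv")))
  det_path <- file.path(dir, paste0(prefix, "_detection.tsv"))
  detection <- if (file.exists(det_path)) read_matrix_tsv(det_path) else NULL
  timecourse(signal, samples, detection, level = level, log2 = log2)
}

#' Read and write GMT gene-list catalogs
#'
#' The GMT convention: one gene list per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param lists named list of character vectors of gene IDs.
#' @param path file path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
write_gmt <- function(lists, path) {
  stopifnot(is.list(lists), !is.null(names(lists)))
  lines <- vapply(names(lists), function(nm) {
    paste(c(nm, nm, lists[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) p[-(1:2)])
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  out
}
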