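#' Construct an EpochSet
#'
#' The package's container for segmented multichannel EEG: a trials x channels
#' x samples array of microvolt values with a time axis in ms (0 = aligning
#' event, half-open spans, 0-based sample convention).
#'
#' @param data numeric array, dim = c(trials, channels, samples).
#' @param time_ms numeric vector of sample times (length = dim 3).
#' @param fs sampling rate (Hz).
#' @param labels channel labels (length = dim 2).
#' @param align `"target"` or `"response"`.
#' @param meta optional named list (seed, config hash, ground truth, ...).
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, fs, labels, align = "target", meta = list()) {
  d <- dim(data)
  if (length(d) != 3L) .fail("epoch data must be trials x channels x samples")
  if (length(time_ms) != d[3L]) .fail("time axis length %d != %d samples", length(time_ms), d[3L])
  if (length(labels) != d[2L]) .fail("%d labels for %d channels", length(labels), d[2L])
  structure(list(data = data, time_ms = as.numeric(time_ms), fs = fs,
                 labels = as.character(labels), align = align, meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, %s-locked [%g, %g) ms\n",
              d[1L], d[2L], d[3L], x$fs, x$align,
              x$time_ms[1L], x$time_ms[length(x$time_ms)] + 1000 / x$fs))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

# channel index lookup with error
chan_index <- function(e, labels) {
  i <- match(labels, e$labels)
  if (anyNA(i)) .fail("unknown channel(s): %s", paste(labels[is.na(i)], collapse = ", "))
  i
}

#' Subset an EpochSet by trials and/or channels
#'
#' @param e an [epoch_set()].
#' @param trials integer or logical trial index (default all).
#' @param channels channel labels or indices (default all).
#' @return an `epoch_set`.
#' @export
subset_epochs <- function(e, trials = NULL, channels = NULL) {
  ti <- if (is.null(trials)) seq_len(dim(e$data)[1L]) else trials
  ci <- if (is.null(channels)) seq_len(dim(e$data)[2L])
        else if (is.character(channels)) chan_index(e, channels) else channels
  epoch_set(e$data[ti, ci, , drop = FALSE], e$time_ms, e$fs, e$labels[ci],
            e$align, e$meta)
}

CONTAINER_VERSION <- 1L

#' Write / read an EpochSet container
#'
#' A versioned on-disk container: `meta.json` (dimensions, time axis, labels,
#' sampling rate, alignment, seed/config hash if present) plus `data.bin`
#' (little-endian float64, trial-major). Round-trips losslessly.
#'
#' @param e an [epoch_set()].
#' @param path directory to create/overwrite.
#' @return `write_epochs`: `path`, invisibly. `read_epochs`: an `epoch_set`.
#' @export
write_epochs <- function(e, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(container_version = CONTAINER_VERSION, dim = dim(e$data),
               time_ms = e$time_ms, fs = e$fs, labels = e$labels,
               align = e$align, meta = e$meta[setdiff(names(e$meta), "ground_truth")])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(e$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) .fail("no meta.json under '%s'", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$container_version) || meta$container_version != CONTAINER_VERSION)
    .fail("container version %s not supported (expected %d)",
          as.character(meta$container_version %||% "<missing>"), CONTAINER_VERSION)
  n <- prod(meta$dim)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8L, endian = "little")
  epoch_set(array(x, dim = meta$dim), meta$time_ms, meta$fs, meta$labels,
            meta$align, as.list(meta$meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trial table as CSV
#'
#' Columns are preserved with their types; missing values are written as empty
#' fields.
#'
#' @param trials a trial table data.frame.
#' @param path CSV file path.
#' @return `read_trial_table`: a `trial_table` data.frame.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("excluded" %in% names(tt)) tt$excluded <- as.logical(tt$excluded)
  class(tt) <- c("trial_table", "data.frame")
  tt
}
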