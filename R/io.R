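# Trial container plus CSV read/write/trim.
#
# Dialect: one file per trial; optional "#key: value" metadata header lines
# (fs, label, free-form meta), then a comma-separated table with header
# time_s, hand_ax..hand_mz, forearm_ax..forearm_mz (19 columns), UTF-8,
# "." decimal, values written with 6 decimal places.

CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")

#' Construct and validate a raw two-sensor trial
#'
#' @param fs sampling rate, Hz.
#' @param hand,forearm data frames with the nine channel columns
#'   `ax,ay,az` (accelerometer, g), `gx,gy,gz` (gyroscope, degrees/second),
#'   `mx,my,mz` (magnetometer, uT); equal row counts.
#' @param label optional class label, 0 (typical) or 1 (CP-like).
#' @param meta named list of free-form metadata.
#' @return An object of class `raw_trial`.
#' @export
raw_trial <- function(fs, hand, forearm, label = NULL, meta = list()) {
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  hand <- as.data.frame(hand); forearm <- as.data.frame(forearm)
  .check_channels(hand, "hand")
  .check_channels(forearm, "forearm")
  if (nrow(hand) != nrow(forearm))
    stop(sprintf("sensor streams desynchronised: hand has %d samples, forearm %d",
                 nrow(hand), nrow(forearm)), call. = FALSE)
  if (!is.null(label)) {
    label <- as.integer(label)
    if (!label %in% c(0L, 1L)) stop("label must be 0 or 1", call. = FALSE)
  }
  structure(list(fs = fs, hand = hand[CHANNELS], forearm = forearm[CHANNELS],
                 label = label, meta = meta),
            class = "raw_trial")
}

.check_channels <- function(df, which) {
  missing <- setdiff(CHANNELS, names(df))
  if (length(missing))
    stop(sprintf("%s sensor is missing channel(s): %s", which,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (ch in CHANNELS) {
    v <- df[[ch]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop(sprintf("%s channel %s contains non-finite values", which, ch),
           call. = FALSE)
  }
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial> %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$hand), x$fs, nrow(x$hand) / x$fs,
              if (!is.null(x$label)) sprintf("  label=%d", x$label) else ""))
  invisible(x)
}

#' Number of samples in a trial
#' @param trial a `raw_trial`.
#' @return Integer sample count (per sensor).
#' @export
n_samples <- function(trial) nrow(trial$hand)

#' Write a trial to the per-trial CSV dialect
#'
#' Metadata (`fs`, `label`, entries of `meta`) are written as leading
#' `#key: value` comment lines, followed by a 19-column CSV
#' (`time_s`, nine `hand_*`, nine `forearm_*` channels) at 6 decimal places.
#' The round trip through [read_trial()] is lossless at that precision.
#'
#' @param trial a valid `raw_trial` with at least one sample.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "raw_trial"))
  if (n_samples(trial) == 0L) stop("cannot write an empty trial", call. = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#fs: %.10g", trial$fs), con)
  if (!is.null(trial$label)) writeLines(sprintf("#label: %d", trial$label), con)
  for (k in names(trial$meta)) {
    v <- trial$meta[[k]]
    if (length(v) == 1L && (is.character(v) || is.numeric(v)))
      writeLines(sprintf("#meta.%s: %s", k, format(v, digits = 10)), con)
  }
  tab <- data.frame(time_s = (seq_len(n_samples(trial)) - 1) / trial$fs)
  for (s in c("hand", "forearm"))
    for (ch in CHANNELS) tab[[paste(s, ch, sep = "_")]] <- trial[[s]][[ch]]
  tab[] <- lapply(tab, function(v) sprintf("%.6f", v))
  utils::write.table(tab, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial from the per-trial CSV dialect
#'
#' Parses the documented dialect, validating that all 19 columns are present
#' and every cell is numeric; a malformed cell raises an error naming its row
#' and column.
#'
#' @param path path to a trial CSV.
#' @param fs_default sampling rate to assume when the file carries no
#'   `#fs:` header, Hz.
#' @return A validated `raw_trial`.
#' @export
read_trial <- function(path, fs_default = 100) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grepl("^#", lines)
  meta_lines <- lines[hdr]
  body <- lines[!hdr]
  if (length(body) < 2L) stop("file contains no data rows", call. = FALSE)

  fs <- fs_default; label <- NULL; meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#([^:]+): ?(.*)$", ln))[[1]]
    if (length(m) != 3L) next
    key <- m[2]; val <- m[3]
    if (key == "fs") fs <- as.numeric(val)
    else if (key == "label") label <- as.integer(val)
    else if (startsWith(key, "meta.")) {
      v <- suppressWarnings(as.numeric(val))
      meta[[sub("^meta\\.", "", key)]] <- if (is.na(v)) val else v
    }
  }

  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  expected <- c("time_s",
                paste("hand", CHANNELS, sep = "_"),
                paste("forearm", CHANNELS, sep = "_"))
  missing <- setdiff(expected, cols)
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)

  cells <- strsplit(body[-1], ",", fixed = TRUE)
  nc <- length(cols)
  bad_len <- which(vapply(cells, length, 1L) != nc)
  if (length(bad_len))
    stop(sprintf("row %d has %d fields, expected %d", bad_len[1] + 1L,
                 length(cells[[bad_len[1]]]), nc), call. = FALSE)
  mat <- matrix(unlist(cells), ncol = nc, byrow = TRUE,
                dimnames = list(NULL, cols))
  num <- suppressWarnings(matrix(as.numeric(mat), ncol = nc,
                                 dimnames = list(NULL, cols)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at data row %d, column '%s'",
                 mat[idx[1], idx[2]], idx[1], cols[idx[2]]), call. = FALSE)
  }
  hand <- as.data.frame(num[, paste("hand", CHANNELS, sep = "_"), drop = FALSE])
  names(hand) <- CHANNELS
  fore <- as.data.frame(num[, paste("forearm", CHANNELS, sep = "_"), drop = FALSE])
  names(fore) <- CHANNELS
  raw_trial(fs = fs, hand = hand, forearm = fore, label = label, meta = meta)
}

#' Remove the unstabilised startup section of a trial
#'
#' Drops the first `round(trim_seconds * fs)` samples from both sensors,
#' keeping the streams synchronised, and records the trim in the metadata.
#'
#' @param trial a `raw_trial`.
#' @param trim_seconds length of the startup section to discard, seconds
#'   (default 1 s).
#' @return The trimmed `raw_trial`.
#' @export
trim_startup <- function(trial, trim_seconds = 1) {
  stopifnot(inherits(trial, "raw_trial"))
  if (trim_seconds < 0) stop("trim_seconds must be >= 0", call. = FALSE)
  n_drop <- round(trim_seconds * trial$fs)
  n <- n_samples(trial)
  if (n_drop >= n)
    stop(sprintf("trim of %.3g s (%d samples) >= trial length %.3g s",
                 trim_seconds, n_drop, n / trial$fs), call. = FALSE)
  if (n_drop == 0L) return(trial)
  keep <- (n_drop + 1L):n
  trial$hand <- trial$hand[keep, , drop = FALSE]
  trial$forearm <- trial$forearm[keep, , drop = FALSE]
  rownames(trial$hand) <- rownames(trial$forearm) <- NULL
  trial$meta$trimmed_seconds <- (trial$meta$trimmed_seconds %||% 0) + trim_seconds
  trial
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset manifest (trial files and labels)
#'
#' @param paths character vector of trial CSV paths.
#' @param labels integer labels (0/1), same length as `paths`.
#' @param path output manifest path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(paths, labels, path) {
  stopifnot(length(paths) == length(labels))
  entries <- Map(function(p, l) list(file = p, label = as.integer(l)),
                 paths, labels)
  names(entries) <- NULL
  if (grepl("\\.json$", path))
    jsonlite::write_json(list(trials = entries), path, auto_unbox = TRUE)
  else
    yaml::write_yaml(list(trials = entries), path)
  invisible(path)
}

#' Read a dataset manifest and load its trials
#'
#' @param path manifest path written by [write_manifest()].
#' @param fs_default default sampling rate for files without an `#fs:` header.
#' @return List of labelled `raw_trial` objects.
#' @export
read_manifest <- function(path, fs_default = 100) {
  man <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  base <- dirname(path)
  lapply(man$trials, function(e) {
    p <- e$file
    if (!file.exists(p)) p <- file.path(base, e$file)
    tr <- read_trial(p, fs_default = fs_default)
    tr$label <- as.integer(e$label)
    tr
  })
}
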