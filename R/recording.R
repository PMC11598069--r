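#' Construct an accelerometer recording
#'
#' An `accel_recording` holds one body side's timestamped 3-axis acceleration
#' trace plus its metadata. After construction the time grid is uniform:
#' `t[i] = t[1] + (i-1)/fs` to within 1 ns.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param a numeric matrix with one row per sample and three columns
#'   (x, y, z acceleration in m/s^2).
#' @param fs sampling rate in Hz.
#' @param side `"L"` or `"R"`.
#' @param exercise_id exercise label, e.g. `"E1"`.
#' @param individual_id participant identifier.
#' @param meta optional named list (age, gender, height_cm, bmi, ...).
#' @return An object of class `accel_recording`.
#' @export
accel_recording <- function(t, a, fs, side = "L", exercise_id = NA_character_,
                            individual_id = NA_character_, meta = list()) {
  a <- as.matrix(a)
  if (ncol(a) != 3L) stop_field("a", "must have exactly 3 axis columns")
  if (length(t) != nrow(a)) stop_field("t", "length must equal the number of sample rows")
  if (length(t) < 2L) stop_field("t", "recording needs at least 2 samples")
  if (any(diff(t) <= 0)) stop_field("t", "sample times must be strictly increasing")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop_field("fs", "must be a positive number")
  if (!side %in% c("L", "R")) stop_field("side", "must be 'L' or 'R'")
  if (any(!is.finite(a))) {
    bad <- which(!is.finite(a), arr.ind = TRUE)[1L, ]
    stop_field("a", sprintf("non-finite acceleration at row %d, axis %s",
                            bad[1L], c("x", "y", "z")[bad[2L]]))
  }
  dt <- diff(t)
  if (any(abs(dt - 1 / fs) > 1e-9)) {
    stop_field("t", "sample times are not on a uniform 1/fs grid; use read_recording() to resample")
  }
  colnames(a) <- c("x", "y", "z")
  structure(list(t = as.numeric(t), a = a, fs = fs, side = side,
                 exercise_id = exercise_id, individual_id = individual_id,
                 meta = meta),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> side %s, %d samples @ %g Hz (%.2f s)\n",
              x$side, length(x$t), x$fs, length(x$t) / x$fs))
  if (!is.na(x$individual_id) || !is.na(x$exercise_id)) {
    cat(sprintf("  individual %s, exercise %s\n", x$individual_id, x$exercise_id))
  }
  invisible(x)
}

#' Number of samples and duration helpers
#' @param rec an `accel_recording`.
#' @return `n_samples()`: integer count; `duration()`: seconds.
#' @export
n_samples <- function(rec) length(rec$t)

#' @rdname n_samples
#' @export
duration <- function(rec) length(rec$t) / rec$fs

default_schema <- c(time = "time_s", x = "ax", y = "ay", z = "az")

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0L) "\t" else ","
}

#' Read an accelerometer recording from delimited text
#'
#' Reads a comma- or tab-delimited file (separator autodetected, gzip
#' accepted) with a header row naming a time column and three axis columns.
#' Timestamps are validated and, when their jitter exceeds 1% of the sample
#' period, the signal is linearly interpolated onto a uniform `1/fs` grid
#' (the DFT downstream assumes uniform sampling).
#'
#' @param path file path.
#' @param schema named character vector mapping roles `time`, `x`, `y`, `z`
#'   to column names; defaults to `time_s`, `ax`, `ay`, `az`.
#' @param fs sampling rate in Hz; if `NULL`, estimated as the reciprocal
#'   median sample interval (snapped to the nearest integer when within 1%).
#' @inheritParams accel_recording
#' @return An [accel_recording()].
#' @export
read_recording <- function(path, schema = default_schema, fs = NULL,
                           side = "L", exercise_id = NA_character_,
                           individual_id = NA_character_, meta = list()) {
  if (!file.exists(path)) stop(sprintf("recording file not found: %s", path), call. = FALSE)
  schema <- c(schema, default_schema[setdiff(names(default_schema), names(schema))])
  df <- read.table(path, header = TRUE, sep = detect_sep(path),
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(schema[c("time", "x", "y", "z")]), names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) < 2L) stop(sprintf("recording %s has fewer than 2 rows", path), call. = FALSE)
  t <- as.numeric(df[[schema[["time"]]]])
  a <- cbind(x = as.numeric(df[[schema[["x"]]]]),
             y = as.numeric(df[[schema[["y"]]]]),
             z = as.numeric(df[[schema[["z"]]]]))
  bad <- which(!is.finite(a), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite acceleration value in %s at row %d, column %s",
                 path, bad[1L, 1L], schema[[c("x", "y", "z")[bad[1L, 2L]]]]),
         call. = FALSE)
  }
  if (anyNA(t) || any(diff(t) <= 0)) {
    bad_row <- if (anyNA(t)) which(is.na(t))[1L] else which(diff(t) <= 0)[1L] + 1L
    stop(sprintf("non-monotone or missing time in %s at row %d (column %s)",
                 path, bad_row, schema[["time"]]), call. = FALSE)
  }
  if (is.null(fs)) {
    fs <- 1 / median(diff(t))
    if (abs(fs - round(fs)) < 0.01 * fs) fs <- round(fs)
  }
  period <- 1 / fs
  if (max(abs(diff(t) - period)) > 0.01 * period) {
    grid <- seq(t[1L], t[length(t)] + period / 2, by = period)
    grid <- grid[grid <= t[length(t)] + 1e-12]
    a <- apply(a, 2L, function(col) approx(t, col, xout = grid)$y)
    t <- grid
  }
  t <- t[1L] + (seq_along(t) - 1L) / fs  # exact uniform grid
  accel_recording(t - t[1L], a, fs, side = side, exercise_id = exercise_id,
                  individual_id = individual_id, meta = meta)
}

#' Write a recording as delimited text
#'
#' Writes the header `time_s,ax,ay,az` and one row per sample at full double
#' precision, the same format [read_recording()] consumes.
#'
#' @param rec an `accel_recording`.
#' @param path output file path (".gz" suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("time_s,ax,ay,az", con)
  rows <- sprintf("%.17g,%.17g,%.17g,%.17g",
                  rec$t, rec$a[, 1L], rec$a[, 2L], rec$a[, 3L])
  writeLines(rows, con)
  invisible(path)
}

#' Trim the start and end of a recording
#'
#' Removes the first `head_s` and last `tail_s` seconds, where movement is
#' typically contaminated by handling the sensor; times are re-zeroed. Two
#' successive trims compose additively in seconds removed.
#'
#' @param rec an `accel_recording`.
#' @param head_s,tail_s seconds to drop at each end (defaults 1 s).
#' @return The trimmed `accel_recording`.
#' @export
trim_recording <- function(rec, head_s = 1, tail_s = 1) {
  if (head_s < 0 || tail_s < 0) stop_field("head_s/tail_s", "must be non-negative")
  dur <- duration(rec)
  if (head_s + tail_s >= dur) {
    stop(sprintf("cannot trim %g + %g s from a %g s recording", head_s, tail_s, dur),
         call. = FALSE)
  }
  rel <- rec$t - rec$t[1L]
  keep <- rel >= head_s - 1e-9 & rel < dur - tail_s - 1e-9
  accel_recording(rel[keep] - rel[keep][1L], rec$a[keep, , drop = FALSE], rec$fs,
                  side = rec$side, exercise_id = rec$exercise_id,
                  individual_id = rec$individual_id, meta = rec$meta)
}

#' Reduce a 3-axis recording to a single channel
#'
#' `magnitude()` returns the per-sample Euclidean norm
#' `sqrt(ax^2 + ay^2 + az^2)`, which is robust to how the phone is oriented
#' on the limb; `channel_series()` additionally allows selecting one raw
#' axis.
#'
#' @param rec an `accel_recording`.
#' @return Numeric vector, one value per sample.
#' @export
magnitude <- function(rec) {
  sqrt(rowSums(rec$a^2))
}

#' @rdname magnitude
#' @param mode `"magnitude"` or one of `"x"`, `"y"`, `"z"`.
#' @export
channel_series <- function(rec, mode = c("magnitude", "x", "y", "z")) {
  mode <- match.arg(mode)
  if (mode == "magnitude") magnitude(rec) else rec$a[, mode]
}

#' Read or build a cohort manifest
#'
#' A manifest is one table listing every recording file: columns
#' `individual_id`, `exercise_id`, `side`, `path`, plus optional participant
#' metadata (`age`, `gender`, `height_cm`, `bmi`). `build_manifest()` is an
#' optional directory-walk adapter for externally deposited datasets: it maps
#' file names of the form `<individual>_<exercise>_<side>.csv` (a documented
#' guess, isolated here so it can change without touching the pipeline) onto
#' the manifest layout. It is not used unless called explicitly.
#'
#' @param path manifest CSV path.
#' @return A data.frame manifest.
#' @export
read_manifest <- function(path) {
  m <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  required <- c("individual_id", "exercise_id", "side", "path")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0L) {
    stop(sprintf("manifest %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!all(m$side %in% c("L", "R"))) stop_field("side", "must be 'L' or 'R'")
  m$path <- ifelse(file.exists(m$path), m$path, file.path(dirname(path), m$path))
  m
}

#' @rdname read_manifest
#' @param dir directory to scan for recording files.
#' @param pattern filename regex with three capture groups:
#'   individual, exercise, side.
#' @export
build_manifest <- function(dir, pattern = "^(.+)_(E[0-9]+)_([LR])\\.csv(\\.gz)?$") {
  files <- list.files(dir, full.names = FALSE)
  hits <- regmatches(files, regexec(pattern, files))
  keep <- lengths(hits) >= 4L
  if (!any(keep)) stop(sprintf("no recording files matching pattern in %s", dir), call. = FALSE)
  parts <- do.call(rbind, lapply(hits[keep], function(h) h[2:4]))
  data.frame(individual_id = parts[, 1L], exercise_id = parts[, 2L],
             side = parts[, 3L], path = file.path(dir, files[keep]),
             stringsAsFactors = FALSE)
}
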