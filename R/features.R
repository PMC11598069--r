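#' Build the time-domain signal matrix from a left/right series pair
#'
#' Splits each side's single-channel series into `M` consecutive segments of
#' `N` samples (one segment per exercise repetition in the default design)
#' and stacks them as columns: columns `1..M` are the left segments in
#' temporal order, columns `M+1..2M` the right segments, giving `Q = 2M`
#' columns in total. Exactly one of `M` or `N` is supplied; the other is
#' derived by floor division and any trailing remainder is discarded.
#'
#' @param left,right numeric single-channel series (e.g. from
#'   [magnitude()]), or two [accel_recording()]s (reduced via `channel`).
#' @param M segments per side, or `NULL`.
#' @param N segment length in samples, or `NULL`.
#' @param fs sampling rate in Hz (taken from the recordings when given).
#' @param channel channel reduction used when recordings are passed.
#' @return An object of class `signal_matrix` with fields `D` (N x Q
#'   matrix), `N`, `M`, `Q`, `fs`, `side` (per column), `pair_index`
#'   (repetition index per column).
#' @export
build_signal_matrix <- function(left, right, M = NULL, N = NULL, fs = NULL,
                                channel = "magnitude") {
  if (inherits(left, "accel_recording")) {
    fs <- left$fs
    left <- channel_series(left, channel)
  }
  if (inherits(right, "accel_recording")) {
    if (is.null(fs)) fs <- right$fs
    right <- channel_series(right, channel)
  }
  if (is.null(fs)) stop_field("fs", "sampling rate required when passing raw series")
  if (is.null(M) == is.null(N)) {
    stop("supply exactly one of M (segments per side) or N (segment length)",
         call. = FALSE)
  }
  len <- min(length(left), length(right))
  if (!is.null(N)) {
    if (len < N) stop(sprintf("series of length %d shorter than one %d-sample segment",
                              len, N), call. = FALSE)
    M <- len %/% N
  } else {
    if (M < 1L) stop_field("M", "must be >= 1")
    N <- len %/% M
    if (N < 1L) stop(sprintf("series of length %d too short for M = %d segments",
                             len, M), call. = FALSE)
  }
  if (abs(length(left) - length(right)) > N) {
    warning(sprintf("left (%d) and right (%d) series differ by more than one segment; using %d samples of each",
                    length(left), length(right), M * N))
  }
  used <- seq_len(M * N)
  D <- cbind(matrix(left[used], nrow = N), matrix(right[used], nrow = N))
  structure(list(D = D, N = as.integer(N), M = as.integer(M), Q = 2L * M,
                 fs = fs, side = rep(c("L", "R"), each = M),
                 pair_index = rep(seq_len(M), 2L)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> N = %d samples x Q = %d columns (M = %d segments/side) @ %g Hz\n",
              x$N, x$Q, x$M, x$fs))
  invisible(x)
}

#' Column-wise DFT of a signal matrix with mean removal
#'
#' Each column has its mean removed and is transformed with the discrete
#' Fourier transform, so the DC coefficient is zero by construction and the
#' spectrum reflects motion about the segment's own baseline. Bin `k`
#' (1-based) corresponds to frequency `(k-1) * fs / N`; the frequency
#' resolution is `fs / N` Hz.
#'
#' @param sm a `signal_matrix`.
#' @return An object of class `spectral_matrix` with fields `G` (N x Q
#'   complex), `freq`, `resolution`, and the bookkeeping of `sm`.
#' @export
dft_columns <- function(sm) {
  stopifnot(inherits(sm, "signal_matrix"))
  centered <- sweep(sm$D, 2L, colMeans(sm$D))
  G <- mvfft(centered)
  structure(list(G = G, freq = (seq_len(sm$N) - 1L) * sm$fs / sm$N,
                 resolution = sm$fs / sm$N, fs = sm$fs, N = sm$N, Q = sm$Q,
                 M = sm$M, side = sm$side, pair_index = sm$pair_index),
            class = "spectral_matrix")
}

#' Relative spectral power of each segment in a frequency band
#'
#' For each column, the fraction of spectral energy falling in the band
#' `[fc1, fc2)`: the numerator sums `|g(k)|^2` over bins whose frequency
#' lies in the half-open band, the denominator over all bins `1..floor(N/2)`
#' (frequencies 0 to just below the Nyquist frequency; the DC bin is zero
#' after mean removal and the Nyquist bin, when N is even, is excluded from
#' both sums). Half-open bands make adjacent bands partition the spectrum
#' with every bin counted exactly once.
#'
#' @param spec a `spectral_matrix` from [dft_columns()].
#' @param band numeric pair `c(fc1, fc2)` in Hz, `0 <= fc1 < fc2 <= fs/2`.
#' @return Numeric vector of length Q with values in `[0, 1]`. A constant
#'   column (zero total power) yields 0 with a warning.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "spectral_matrix"))
  if (length(band) != 2L || band[1L] < 0 || band[1L] >= band[2L] || band[2L] > spec$fs / 2) {
    stop_field("band", sprintf("need 0 <= fc1 < fc2 <= fs/2 = %g", spec$fs / 2))
  }
  half <- seq_len(spec$N %/% 2L)
  pow <- abs(spec$G[half, , drop = FALSE])^2
  f <- spec$freq[half]
  in_band <- f >= band[1L] & f < band[2L]
  total <- colSums(pow)
  e <- ifelse(total > 0, colSums(pow[in_band, , drop = FALSE]) / total, 0)
  if (any(total == 0)) {
    warning(sprintf("%d constant column(s) have zero spectral power; band power set to 0",
                    sum(total == 0)))
  }
  unname(e)
}

#' Build the pattern and target matrices for symmetry and classification
#'
#' Assembles the pattern matrix `P` (features x segments) from a selection
#' of time-domain features (`mean`, `std`: sample standard deviation with
#' the n-1 denominator) and one relative band-power row per frequency band,
#' plus the one-hot target matrix `T` (2 x Q; class 1 = left, class 2 =
#' right) used by the classifiers. Columns keep the
#' `[L(1)..L(M), R(1)..R(M)]` ordering of the signal matrix.
#'
#' @param sm a `signal_matrix`.
#' @param spec optional precomputed `spectral_matrix`; computed from `sm`
#'   when band powers are requested and `spec` is `NULL`.
#' @param bands list of `c(fc1, fc2)` pairs in Hz; defaults to
#'   `[0.5, 3)` and `[3, 10)` Hz, covering typical exercise fundamentals
#'   and their low harmonics.
#' @param features subset of `c("mean", "std", "bandpower")`;
#'   `"bandpower"` expands to one row per band.
#' @return An object of class `feature_set` with fields `P`,
#'   `feature_names`, `T`, `bands`, `M`, `Q`, `side`, `pair_index`.
#' @export
build_feature_set <- function(sm, spec = NULL,
                              bands = list(c(0.5, 3), c(3, 10)),
                              features = c("mean", "std", "bandpower")) {
  stopifnot(inherits(sm, "signal_matrix"))
  features <- unique(features)
  if (length(features) == 0L) stop_field("features", "selection must be non-empty")
  bad <- setdiff(features, c("mean", "std", "bandpower"))
  if (length(bad) > 0L) {
    stop_field("features", sprintf("unknown feature(s): %s", paste(bad, collapse = ", ")))
  }
  rows <- list()
  if ("mean" %in% features) rows[["mean"]] <- colMeans(sm$D)
  if ("std" %in% features) rows[["std"]] <- apply(sm$D, 2L, sd)
  if ("bandpower" %in% features) {
    if (is.null(spec)) spec <- dft_columns(sm)
    for (b in bands) {
      rows[[sprintf("bandpower[%g,%g)", b[1L], b[2L])]] <- band_power(spec, b)
    }
  }
  P <- do.call(rbind, rows)
  rownames(P) <- names(rows)
  target <- rbind(L = as.numeric(sm$side == "L"), R = as.numeric(sm$side == "R"))
  structure(list(P = P, feature_names = names(rows), T = target,
                 bands = if ("bandpower" %in% features) bands else list(),
                 M = sm$M, Q = sm$Q, side = sm$side, pair_index = sm$pair_index,
                 fs = sm$fs),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d feature(s) x %d segments (M = %d pairs)\n",
              nrow(x$P), x$Q, x$M))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Export or import a feature set
#'
#' CSV layout: one row per feature (first column the feature name), one
#' column per segment with header labels `L1..LM, R1..RM`; values are
#' written at full double precision. The JSON format archives the full
#' object (pattern matrix, targets, bands, bookkeeping).
#'
#' @param fset a `feature_set`.
#' @param path output/input file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `write_feature_set()`: `path` invisibly; `read_feature_set()`:
#'   a `feature_set`.
#' @export
write_feature_set <- function(fset, path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "csv"
  if (format == "json") {
    payload <- list(P = unname(fset$P), feature_names = fset$feature_names,
                    bands = fset$bands, M = fset$M, Q = fset$Q,
                    side = fset$side, pair_index = fset$pair_index, fs = fset$fs)
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  } else {
    labels <- paste0(fset$side, fset$pair_index)
    df <- data.frame(feature = fset$feature_names,
                     matrix(sprintf("%.17g", fset$P), nrow = nrow(fset$P)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("feature", labels)
    # feature names may contain commas (band labels), so quote that column
    write.table(df, path, sep = ",", row.names = FALSE, quote = 1L)
  }
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "csv"
  if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    P <- payload$P
    if (!is.matrix(P)) P <- matrix(P, nrow = length(payload$feature_names))
    side <- payload$side
    feature_names <- payload$feature_names
    bands <- lapply(seq_len(nrow(as.matrix(payload$bands))), function(i) as.matrix(payload$bands)[i, ])
    if (length(payload$bands) == 0L) bands <- list()
    M <- payload$M; fs <- payload$fs; pair_index <- payload$pair_index
  } else {
    df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                     stringsAsFactors = FALSE)
    feature_names <- df$feature
    P <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(P) <- "double"
    labels <- colnames(P)
    side <- substr(labels, 1L, 1L)
    pair_index <- as.integer(substring(labels, 2L))
    M <- sum(side == "L"); fs <- NA_real_; bands <- list()
  }
  rownames(P) <- feature_names
  colnames(P) <- NULL
  target <- rbind(L = as.numeric(side == "L"), R = as.numeric(side == "R"))
  structure(list(P = P, feature_names = feature_names, T = target,
                 bands = bands, M = as.integer(M), Q = ncol(P), side = side,
                 pair_index = as.integer(pair_index), fs = fs),
            class = "feature_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
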