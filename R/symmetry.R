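#' Percentage symmetry index of a left/right feature pair
#'
#' For non-negative feature values (standard deviation, band power) of a
#' matched left/right segment pair, the index
#' \deqn{c = 50 \, |F_L - F_R| / (F_L + F_R)}
#' lies in `[0, 50]`: 0 for identical features, 50 when one side's feature
#' vanishes. It is invariant to a common positive rescaling of both inputs
#' and symmetric under exchanging sides. Both inputs zero (no motion on
#' either side) is treated as perfect symmetry, `c = 0`. With
#' `signed = TRUE` the absolute value is dropped, so positive values mean
#' the left side dominates.
#'
#' @param f_l,f_r non-negative feature values (vectorized).
#' @param signed keep the sign of `F_L - F_R`? Default `FALSE`.
#' @return Numeric vector of indices on the percent scale.
#' @export
symmetry_index <- function(f_l, f_r, signed = FALSE) {
  if (any(f_l < 0) || any(f_r < 0)) {
    stop("symmetry_index() requires non-negative feature values", call. = FALSE)
  }
  denom <- f_l + f_r
  c_val <- ifelse(denom == 0, 0, 50 * (f_l - f_r) / denom)
  if (!signed) c_val <- abs(c_val)
  c_val
}

#' Global symmetry criterion of a feature set
#'
#' Pairs left segment `q` with right segment `q` (columns `q` and `M + q` of
#' the pattern matrix) for `q = 1..M`, computes the symmetry index per pair
#' and per feature in the selected subset, and averages: first over the `M`
#' pairs within each feature, then over the features. The normalizer of the
#' inner average is the number of left/right pairs actually summed (`M`),
#' since one index exists per pair, not per column.
#'
#' @param fset a `feature_set` from [build_feature_set()].
#' @param psi character vector of feature names to use, or a preset name
#'   passed to [psi_preset()] (`"frequency"` or `"mixed"`, the default).
#' @param signed propagate signed indices (see [symmetry_index()]); the
#'   scalar criterion always averages unsigned magnitudes.
#' @param exercise_id,individual_id labels carried into the result.
#' @return An object of class `symmetry_result`: `c` (M x R matrix of
#'   per-pair, per-feature indices), `C` (scalar criterion), `psi`, labels,
#'   and `degenerate` (count of 0/0 pairs scored as 0).
#' @export
global_criterion <- function(fset, psi = "mixed", signed = FALSE,
                             exercise_id = NULL, individual_id = NULL) {
  stopifnot(inherits(fset, "feature_set"))
  if (length(psi) == 1L && psi %in% c("frequency", "mixed")) {
    psi <- psi_preset(fset, psi)
  }
  if (length(psi) == 0L) stop_field("psi", "feature subset must be non-empty")
  missing_f <- setdiff(psi, fset$feature_names)
  if (length(missing_f) > 0L) {
    stop_field("psi", sprintf("feature(s) not in the set: %s",
                              paste(missing_f, collapse = ", ")))
  }
  M <- fset$M
  if (fset$Q != 2L * M || !all(fset$side == rep(c("L", "R"), each = M))) {
    stop("feature set columns are not paired as [L(1)..L(M), R(1)..R(M)]",
         call. = FALSE)
  }
  FL <- fset$P[psi, seq_len(M), drop = FALSE]
  FR <- fset$P[psi, M + seq_len(M), drop = FALSE]
  degenerate <- sum(FL + FR == 0)
  cmat <- vapply(seq_along(psi), function(r) {
    symmetry_index(FL[r, ], FR[r, ], signed = signed)
  }, numeric(M))
  cmat <- matrix(cmat, nrow = M, ncol = length(psi))  # rows = pairs, cols = features
  colnames(cmat) <- psi
  C <- mean(colMeans(abs(cmat)))
  structure(list(c = cmat, C = C, psi = psi,
                 exercise_id = exercise_id %||% fset$exercise_id,
                 individual_id = individual_id %||% fset$individual_id,
                 degenerate = degenerate),
            class = "symmetry_result")
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf("<symmetry_result> C = %.1f over %d pair(s) x %d feature(s)\n",
              x$C, nrow(x$c), ncol(x$c)))
  if (x$degenerate > 0) cat(sprintf("  %d degenerate (0/0) pair-feature cell(s)\n", x$degenerate))
  invisible(x)
}

#' Feature-subset presets for the symmetry criterion
#'
#' `"frequency"` selects the relative band-power features only;
#' `"mixed"` adds the time-domain standard deviation. The segment mean is
#' excluded from both: it can be negative (or reflect gravity offset rather
#' than motion), which the symmetry index is not defined for.
#'
#' @param fset a `feature_set`.
#' @param preset `"frequency"` or `"mixed"`.
#' @return Character vector of feature names.
#' @export
psi_preset <- function(fset, preset = c("mixed", "frequency")) {
  preset <- match.arg(preset)
  bp <- grep("^bandpower", fset$feature_names, value = TRUE)
  psi <- if (preset == "frequency") bp else c(intersect("std", fset$feature_names), bp)
  if (length(psi) == 0L) {
    stop(sprintf("preset '%s' selects no features from: %s", preset,
                 paste(fset$feature_names, collapse = ", ")), call. = FALSE)
  }
  psi
}

#' Build a symmetry table from a matrix or from per-cell results
#'
#' The table mirrors the usual study layout: one row per individual, one
#' column per exercise, with the global criterion `C` in each cell, plus
#' per-individual row means, per-exercise column means and column sample
#' standard deviations (n-1 denominator). Values are stored at full
#' precision and rounded (1 decimal) only when printed or written.
#'
#' `aggregate_table()` assembles the table from a collection of
#' [global_criterion()] results; duplicate (individual, exercise) cells are
#' an error, missing cells are `NA` and excluded from the summaries.
#'
#' @param values numeric matrix of criterion values, individuals x
#'   exercises, with dimnames.
#' @return An object of class `symmetry_table`: `values`, `row_means`,
#'   `col_means`, `col_stds`.
#' @export
symmetry_table <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- as.character(seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("E", seq_len(ncol(values)))
  structure(list(values = values,
                 row_means = rowMeans(values, na.rm = TRUE),
                 col_means = colMeans(values, na.rm = TRUE),
                 col_stds = apply(values, 2L, sd, na.rm = TRUE)),
            class = "symmetry_table")
}

#' @rdname symmetry_table
#' @param results list of `symmetry_result` objects, each labeled with
#'   `individual_id` and `exercise_id`.
#' @export
aggregate_table <- function(results) {
  if (length(results) == 0L) stop("no symmetry results to aggregate", call. = FALSE)
  inds <- vapply(results, function(r) as.character(r$individual_id), character(1))
  exs <- vapply(results, function(r) as.character(r$exercise_id), character(1))
  if (anyNA(inds) || anyNA(exs)) {
    stop("every result needs individual_id and exercise_id labels", call. = FALSE)
  }
  key <- paste(inds, exs, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("duplicate cell for individual '%s', exercise '%s'",
                 sub("\r.*", "", dup), sub(".*\r", "", dup)), call. = FALSE)
  }
  rows <- unique(inds)
  cols <- unique(exs)
  values <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_along(results)) values[inds[i], exs[i]] <- results[[i]]$C
  symmetry_table(values)
}

#' @export
print.symmetry_table <- function(x, ...) {
  disp <- cbind(round(x$values, 1), Mean = round(x$row_means, 1))
  disp <- rbind(disp, Mean = c(round(x$col_means, 1), NA),
                Std = c(round(x$col_stds, 1), NA))
  print(disp, na.print = "")
  invisible(x)
}

#' Write a symmetry table as CSV or JSON
#'
#' CSV mirrors the printed layout (individuals x exercises with Mean column
#' and Mean/Std rows, 1 decimal); JSON stores full-precision values plus the
#' summaries for programmatic use, with an optional provenance field.
#'
#' @param tab a `symmetry_table`.
#' @param path output path.
#' @param format `"csv"` or `"json"` (default from extension).
#' @param provenance optional named list embedded in the JSON output
#'   (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_symmetry_table <- function(tab, path, format = NULL, provenance = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "csv"
  if (format == "json") {
    # named vectors become JSON objects (jsonlite drops names on arrays)
    payload <- list(individuals = rownames(tab$values),
                    exercises = colnames(tab$values),
                    values = unname(tab$values),
                    row_means = as.list(tab$row_means),
                    col_means = as.list(tab$col_means),
                    col_stds = as.list(tab$col_stds))
    if (!is.null(provenance)) payload$provenance <- provenance
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  } else {
    disp <- cbind(round(tab$values, 1), Mean = round(tab$row_means, 1))
    disp <- rbind(disp, Mean = c(round(tab$col_means, 1), NA),
                  Std = c(round(tab$col_stds, 1), NA))
    df <- data.frame(individual = rownames(disp), disp, check.names = FALSE)
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}
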