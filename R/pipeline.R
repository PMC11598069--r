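#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end pipeline uses. Unknown
#' fields are rejected, and the full configuration (plus its hash, see
#' [config_hash()]) is embedded in every JSON output for provenance.
#'
#' @param trim_head,trim_tail seconds trimmed off each recording
#'   (default 1 s each).
#' @param channel `"magnitude"` or an axis name (`"x"`, `"y"`, `"z"`).
#' @param M segments per side (default 10, one per repetition), or `NULL`
#'   when `N` is given.
#' @param N segment length in samples, or `NULL` when `M` is given.
#' @param bands list of frequency bands in Hz for the band-power features.
#' @param psi symmetry feature preset: `"mixed"` or `"frequency"`.
#' @param classifiers character subset of `c("svm", "bayes", "nn")`;
#'   empty vector skips classification.
#' @param S1 NN hidden units.
#' @param seed master RNG seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_head = 1, trim_tail = 1,
                            channel = "magnitude", M = 10, N = NULL,
                            bands = list(c(0.5, 3), c(3, 10)),
                            psi = "mixed",
                            classifiers = c("svm", "bayes", "nn"),
                            S1 = 10, seed = 1) {
  if (!channel %in% c("magnitude", "x", "y", "z")) {
    stop_field("channel", "must be 'magnitude', 'x', 'y' or 'z'")
  }
  if (is.null(M) == is.null(N)) stop_field("M/N", "supply exactly one of M or N")
  if (!psi %in% c("mixed", "frequency")) stop_field("psi", "must be 'mixed' or 'frequency'")
  bad <- setdiff(classifiers, c("svm", "bayes", "nn"))
  if (length(bad) > 0L) stop_field("classifiers", paste("unknown:", paste(bad, collapse = ", ")))
  if (trim_head < 0 || trim_tail < 0) stop_field("trim_head/trim_tail", "must be >= 0")
  for (b in bands) {
    if (length(b) != 2L || b[1L] < 0 || b[1L] >= b[2L]) {
      stop_field("bands", "each band must be c(fc1, fc2) with 0 <= fc1 < fc2")
    }
  }
  structure(list(trim_head = trim_head, trim_tail = trim_tail,
                 channel = channel, M = M, N = N, bands = bands, psi = psi,
                 classifiers = classifiers, S1 = S1, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are `pipeline_config()`
#'   arguments; unknown keys are an error.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(raw$bands)) raw$bands <- lapply(raw$bands, as.numeric)
  do.call(pipeline_config, raw)
}

#' Hash a pipeline configuration
#'
#' MD5 digest of the canonical JSON serialization; any change to any field
#' yields a different hash. Embedded in every JSON output so results can be
#' traced to the exact configuration that produced them.
#'
#' @param config a `pipeline_config`.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full symmetry and classification pipeline over a cohort
#'
#' For every (individual, exercise) cell of the manifest with both sides
#' present: read and trim both recordings, reduce to a single channel,
#' segment into the signal matrix, extract features, compute the global
#' symmetry criterion, and (optionally) run leave-one-out cross-validation
#' for each configured classifier. Cells missing a side are skipped with a
#' warning. Outputs are deterministic given `config$seed`.
#'
#' @param manifest data.frame from [read_manifest()] (or an in-memory list
#'   of recording pairs from [generate_cohort()], passed as a
#'   `synth_cohort`).
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `symmetry`
#'   ([symmetry_table()]), `reports` (individual -> exercise -> method),
#'   `log` (stage counters, including `n_repetition_tests` = segments per
#'   side summed over processed cells), `config`, `config_hash`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  pairs <- collect_pairs(manifest, config)
  if (length(pairs) == 0L) stop("manifest yields no usable recording pairs", call. = FALSE)
  results <- list()
  reports <- list()
  n_segments <- 0L
  n_tests <- 0L
  for (cell in pairs) {
    sm <- build_signal_matrix(cell$L, cell$R, M = config$M, N = config$N,
                              channel = config$channel)
    fset <- build_feature_set(sm, bands = config$bands,
                              features = c("mean", "std", "bandpower"))
    res <- global_criterion(fset, psi = config$psi,
                            exercise_id = cell$exercise_id,
                            individual_id = cell$individual_id)
    results[[length(results) + 1L]] <- res
    n_segments <- n_segments + sm$Q
    n_tests <- n_tests + sm$M
    if (length(config$classifiers) > 0L) {
      psi <- psi_preset(fset, config$psi)
      cell_reports <- lapply(config$classifiers, function(m) {
        loocv(m, fset, seed = config$seed, psi = psi, S1 = config$S1)
      })
      names(cell_reports) <- config$classifiers
      reports[[cell$individual_id]][[cell$exercise_id]] <- cell_reports
    }
  }
  structure(list(symmetry = aggregate_table(results),
                 reports = reports,
                 log = list(n_pairs = length(pairs), n_segments = n_segments,
                            n_repetition_tests = n_tests,
                            n_skipped = attr(pairs, "n_skipped")),
                 config = config, config_hash = config_hash(config)),
            class = "pipeline_result")
}

# Resolve a manifest (or an in-memory synthetic cohort) into trimmed,
# per-cell L/R recording pairs.
collect_pairs <- function(manifest, config) {
  n_skipped <- 0L
  trim_cfg <- function(rec) {
    if (config$trim_head + config$trim_tail == 0) rec
    else trim_recording(rec, config$trim_head, config$trim_tail)
  }
  if (inherits(manifest, "synth_cohort")) {
    pairs <- lapply(manifest, function(cell) {
      list(individual_id = cell$individual_id, exercise_id = cell$exercise_id,
           L = trim_cfg(cell$pair$L), R = trim_cfg(cell$pair$R))
    })
  } else {
    if (!is.data.frame(manifest) || nrow(manifest) == 0L) {
      stop("empty manifest", call. = FALSE)
    }
    cells <- unique(manifest[, c("individual_id", "exercise_id")])
    pairs <- list()
    for (i in seq_len(nrow(cells))) {
      sel <- manifest$individual_id == cells$individual_id[i] &
        manifest$exercise_id == cells$exercise_id[i]
      rows <- manifest[sel, ]
      if (!all(c("L", "R") %in% rows$side)) {
        warning(sprintf("individual %s, exercise %s: missing side, cell skipped",
                        cells$individual_id[i], cells$exercise_id[i]))
        n_skipped <- n_skipped + 1L
        next
      }
      get_side <- function(s) {
        row <- rows[rows$side == s, ][1L, ]
        trim_cfg(read_recording(row$path, side = s,
                                exercise_id = row$exercise_id,
                                individual_id = row$individual_id))
      }
      pairs[[length(pairs) + 1L]] <- list(individual_id = cells$individual_id[i],
                                          exercise_id = cells$exercise_id[i],
                                          L = get_side("L"), R = get_side("R"))
    }
  }
  attr(pairs, "n_skipped") <- n_skipped
  pairs
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d pair(s), %d segments, %d repetition tests\n",
              x$log$n_pairs, x$log$n_segments, x$log$n_repetition_tests))
  cat(sprintf("  config %s\n", x$config_hash))
  print(x$symmetry)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Writes `symmetry.csv` / `symmetry.json`, and when classification ran,
#' `reports.csv` / `reports.json`, plus `config.json`. Every JSON file
#' embeds the configuration hash; stored values are full precision, CSVs
#' are rounded for presentation only.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(config_hash = result$config_hash)
  write_symmetry_table(result$symmetry, file.path(dir, "symmetry.csv"))
  write_symmetry_table(result$symmetry, file.path(dir, "symmetry.json"),
                       provenance = prov)
  if (length(result$reports) > 0L) {
    write_reports(result$reports, file.path(dir, "reports.csv"))
    write_reports(result$reports, file.path(dir, "reports.json"), provenance = prov)
  }
  jsonlite::write_json(c(unclass(result$config), prov),
                       file.path(dir, "config.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
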