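#' Published reference tables of the originating rehabilitation study
#'
#' Two small tables transcribed from the study this methodology follows,
#' shipped as plain-text CSVs so the package's aggregation arithmetic can be
#' validated without downloading the study's raw recordings.
#'
#' `reference_participants()` returns the 16-participant cohort description
#' (age in years, gender, height in cm, BMI in kg/m^2).
#' `reference_symmetry()` returns the published global symmetry criterion
#' values (one row per individual, one column per exercise E1--E8, mixed-
#' domain features) as a [symmetry_table()], whose row/column summaries are
#' recomputed from the cells rather than copied.
#'
#' @return `reference_participants()`: a data.frame;
#'   `reference_symmetry()`: a `symmetry_table`.
#' @export
reference_participants <- function() {
  read.table(system.file("extdata", "reference_participants.csv",
                         package = "accsym", mustWork = TRUE),
             header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' @rdname reference_participants
#' @export
reference_symmetry <- function() {
  df <- read.table(system.file("extdata", "reference_symmetry.csv",
                               package = "accsym", mustWork = TRUE),
                   header = TRUE, sep = ",", check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L])
  rownames(values) <- as.character(df$individual)
  symmetry_table(values)
}

#' Summary statistics of a participant table
#'
#' Mean and sample standard deviation (n-1 denominator) of the numeric
#' participant descriptors, as printed in cohort description tables.
#'
#' @param participants data.frame from [reference_participants()] (or any
#'   table with numeric columns among `age`, `height_cm`, `bmi`).
#' @return Data.frame with one row per descriptor: `mean` and `sd`.
#' @export
cohort_summary <- function(participants = reference_participants()) {
  cols <- intersect(c("age", "height_cm", "bmi"), names(participants))
  do.call(rbind, lapply(cols, function(cl) {
    data.frame(descriptor = cl, mean = mean(participants[[cl]]),
               sd = sd(participants[[cl]]), stringsAsFactors = FALSE)
  }))
}
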