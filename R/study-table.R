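#' @importFrom stats coef fitted predict residuals sd simulate
#' @importFrom utils read.csv write.csv
NULL

# canonical factor levels; stored labels must match these exactly
.gvs_measures   <- c("ocular_torsion", "visual_tilt")
.gvs_polarities <- c("left_anodal", "right_anodal")
.gvs_table_cols <- c("intensity_mA", "polarity", "measure",
                     "mean_deg", "sd_deg", "min_deg", "max_deg", "n")

.gvs_direction_note <- paste(
  "Ocular torsion occurs toward the anode, visual tilt away from it;",
  "all stored rotations are unsigned magnitudes (direction is metadata only).")

#' Resolve a measure label
#'
#' Accepts the canonical labels `"ocular_torsion"` / `"visual_tilt"` as well as
#' the short forms `"torsion"` / `"tilt"`.
#' @keywords internal
#' @noRd
match_measure <- function(measure) {
  stopifnot(is.character(measure), length(measure) == 1L)
  out <- switch(measure,
                ocular_torsion = , torsion = "ocular_torsion",
                visual_tilt    = , tilt    = "visual_tilt",
                NA_character_)
  if (is.na(out)) {
    stop("unknown measure label '", measure, "'; expected one of ",
         paste(.gvs_measures, collapse = ", "), call. = FALSE)
  }
  out
}

new_study_table <- function(df) {
  df <- as.data.frame(df)[, .gvs_table_cols]
  rownames(df) <- NULL
  structure(df,
            direction_note = .gvs_direction_note,
            class = c("study_table", "data.frame"))
}

#' Validate a study summary table
#'
#' Checks the per-cell invariants of a galvanic-vestibular-stimulation summary
#' table: positive intensities, known polarity and measure labels, `n >= 1`,
#' `sd >= 0`, `min <= mean <= max`, all magnitudes nonnegative (rotations are
#' stored unsigned), no duplicated cells, and that every (intensity, measure)
#' pair present carries both stimulation polarities.
#'
#' @param x A data frame in the study-table layout (see [read_study_table()]).
#' @return `x`, invisibly, as a validated `study_table`.
#' @export
validate_study_table <- function(x) {
  x <- as.data.frame(x)
  if (!identical(sort(names(x)), sort(.gvs_table_cols))) {
    stop("malformed study table: expected columns ",
         paste(.gvs_table_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("intensity_mA", "mean_deg", "sd_deg", "min_deg", "max_deg", "n")
  for (cl in num_cols) {
    if (!is.numeric(x[[cl]]) || anyNA(x[[cl]])) {
      stop("malformed study table: column '", cl, "' must be numeric with no ",
           "missing values", call. = FALSE)
    }
  }
  bad_label <- function(col, levels) which(!(x[[col]] %in% levels))
  i <- bad_label("polarity", .gvs_polarities)
  if (length(i)) stop("unknown polarity label in row ", i[1L], ": '",
                      x$polarity[i[1L]], "'", call. = FALSE)
  i <- bad_label("measure", .gvs_measures)
  if (length(i)) stop("unknown measure label in row ", i[1L], ": '",
                      x$measure[i[1L]], "'", call. = FALSE)

  check <- function(ok, what) {
    if (any(!ok)) stop("invalid study table row ", which(!ok)[1L], ": ", what,
                       call. = FALSE)
  }
  check(x$intensity_mA > 0, "intensity must be strictly positive")
  check(x$n >= 1 & x$n == round(x$n), "n must be a whole number >= 1")
  check(x$sd_deg >= 0, "sd must be nonnegative")
  check(x$min_deg >= 0 & x$mean_deg >= 0,
        "magnitudes must be nonnegative (unsigned convention)")
  check(x$min_deg <= x$mean_deg & x$mean_deg <= x$max_deg,
        "mean must lie within [min, max]")

  key <- paste(x$intensity_mA, x$polarity, x$measure)
  if (anyDuplicated(key)) {
    stop("duplicated cell in row ", which(duplicated(key))[1L], call. = FALSE)
  }
  pair <- paste(x$intensity_mA, x$measure)
  n_pol <- tapply(x$polarity, pair, function(p) length(unique(p)))
  if (any(n_pol != 2L)) {
    stop("cell (", names(n_pol)[n_pol != 2L][1L], ") is present for only one ",
         "stimulation polarity; each (intensity, measure) pair needs both arms",
         call. = FALSE)
  }
  invisible(new_study_table(x))
}

#' Read a study summary table
#'
#' Reads a delimiter-separated summary table with one row per
#' (intensity, polarity, measure) cell and columns `intensity_mA`, `polarity`,
#' `measure`, `mean_deg`, `sd_deg`, `min_deg`, `max_deg`, `n`. Cells that were
#' never measured are absent rows, not zero rows. The same layout is shared by
#' the packaged Zink et al. (1998) table and by synthetic studies from
#' [simulate_study()], so both flow through the identical pipeline.
#'
#' @param path Path to a CSV file in the layout above.
#' @return A `study_table`: a data frame carrying a `direction_note` attribute
#'   recording the sign conventions (torsion toward the anode, tilt away from
#'   it; magnitudes stored unsigned).
#' @seealso [write_study_table()], [zink1998_table()], [average_bilateral()]
#' @export
read_study_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .gvs_table_cols)) {
    stop("malformed study table file '", path, "': expected header ",
         paste(.gvs_table_cols, collapse = ","), call. = FALSE)
  }
  validate_study_table(df)
}

#' Write a study summary table
#'
#' @param x A `study_table` (or data frame in the same layout).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  x <- validate_study_table(x)
  write.csv(as.data.frame(x)[, .gvs_table_cols], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The Zink et al. (1998) summary table
#'
#' Descriptive statistics of static ocular torsion and perceived visual tilt
#' (degrees, unsigned) under unipolar direct-current galvanic vestibular
#' stimulation at 1--7 mA, for left- and right-anodal polarity, as published by
#' Zink et al. (1998, Electroencephalography and Clinical Neurophysiology, 107,
#' 200--205). Torsion was measured at 1.0, 1.5, 2.0, 3.0, 4.0, 5.0, 6.0 and
#' 7.0 mA; tilt at 1.5, 2.0, 2.5 and 3.0 mA. A visual-tilt measurement that the
#' original report attributes inconsistently to 4.5 mA (its figure shows
#' 3.5 mA and its table neither) is excluded from the packaged table.
#'
#' @return A `study_table` with 24 cells (16 torsion, 8 tilt).
#' @examples
#' tab <- zink1998_table()
#' average_bilateral(tab, "torsion")
#' @export
zink1998_table <- function() {
  read_study_table(system.file("extdata", "zink1998_table1.csv",
                               package = "gvsfit", mustWork = TRUE))
}

#' Standard error of the mean for a summary cell
#'
#' @param sd_deg Cell standard deviation(s), degrees.
#' @param n Cell subject count(s), `>= 1`.
#' @return `sd_deg / sqrt(n)`, vectorised.
#' @examples
#' cell_sem(0.4, 6)
#' @export
cell_sem <- function(sd_deg, n) {
  stopifnot(is.numeric(sd_deg), is.numeric(n))
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(sd_deg < 0)) stop("sd must be nonnegative", call. = FALSE)
  sd_deg / sqrt(n)
}

#' Bilaterally averaged response series for one measure
#'
#' Collapses a two-polarity study table into the series the models are fitted
#' to: at every intensity where both stimulation arms were measured, the
#' unsigned left- and right-anodal cell means are averaged arithmetically.
#' The series standard error is a display convention only (never used in
#' fitting): each arm contributes `sd/sqrt(n)` and the two arms are averaged.
#'
#' @param table A `study_table`.
#' @param measure `"ocular_torsion"`/`"torsion"` or `"visual_tilt"`/`"tilt"`.
#' @return A `measure_series`: data frame with columns `intensity_mA`
#'   (strictly increasing), `mean_deg`, `sem_deg`, and a `measure` attribute.
#' @examples
#' average_bilateral(zink1998_table(), "tilt")
#' @export
average_bilateral <- function(table, measure) {
  table <- validate_study_table(table)
  measure <- match_measure(measure)
  rows <- table[table$measure == measure, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("measure '", measure, "' is not present in the table", call. = FALSE)
  }
  per <- lapply(split(rows, rows$intensity_mA), function(cells) {
    # validation guarantees exactly one cell per arm
    data.frame(intensity_mA = cells$intensity_mA[1L],
               mean_deg = mean(cells$mean_deg),
               sem_deg = mean(cell_sem(cells$sd_deg, cells$n)))
  })
  out <- do.call(rbind, per)
  out <- out[order(out$intensity_mA), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, measure = measure, class = c("measure_series", "data.frame"))
}

#' Coerce to a measure series
#'
#' Accepts an existing `measure_series` or a plain data frame with columns
#' `intensity_mA` and `mean_deg` (and optionally `sem_deg`); intensities must
#' be strictly positive and unique, means nonnegative. Rows are sorted by
#' intensity.
#'
#' @param x Object to coerce.
#' @param measure Measure label attached to the result when `x` carries none.
#' @return A `measure_series`.
#' @export
as_measure_series <- function(x, measure = "ocular_torsion") {
  if (inherits(x, "measure_series")) return(x)
  x <- as.data.frame(x)
  if (!all(c("intensity_mA", "mean_deg") %in% names(x))) {
    stop("a measure series needs columns 'intensity_mA' and 'mean_deg'",
         call. = FALSE)
  }
  if (nrow(x) == 0L) stop("empty measure series", call. = FALSE)
  if (is.null(x$sem_deg)) x$sem_deg <- rep(0, nrow(x))
  x <- x[order(x$intensity_mA), c("intensity_mA", "mean_deg", "sem_deg")]
  if (any(x$intensity_mA <= 0)) {
    stop("intensities must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(x$intensity_mA)) {
    stop("duplicated intensities in measure series", call. = FALSE)
  }
  if (any(x$mean_deg < 0)) {
    stop("series means must be nonnegative (unsigned convention)",
         call. = FALSE)
  }
  rownames(x) <- NULL
  structure(x, measure = match_measure(measure),
            class = c("measure_series", "data.frame"))
}
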