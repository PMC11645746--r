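#' Read a visual-field table from CSV
#'
#' The interchange format is one test per row with columns `patient_id`,
#' `eye` (`right`/`left`), `age` (years), `stimulus` (`III`/`V`),
#' `fp_rate` (false-positive catch-trial rate, fraction in \[0, 1\]) and
#' `loc_01` .. `loc_52` (raw sensitivities in dB, in the [vf_grid()]
#' ordering). Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param grid Grid convention (only its length is checked).
#' @return A `vf_table`: a data frame of validated visual fields.
#' @export
read_vf_table <- function(path, grid = vf_grid()) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_vf_table(df, grid = grid)
}

#' Validate a data frame of visual fields
#'
#' @param df Data frame with the columns described in [read_vf_table()].
#' @param grid Grid convention.
#' @return The validated data frame with class `vf_table`.
#' @export
as_vf_table <- function(df, grid = vf_grid()) {
  needed <- c("patient_id", "eye", "age", "stimulus", "fp_rate", loc_cols())
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("visual-field table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot(length(loc_cols()) == nrow(grid))
  for (cc in c("age", "fp_rate", loc_cols())) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value in column '%s' at row %d", cc, bad[1]),
             call. = FALSE)
      }
      df[[cc]] <- vn
    }
  }
  bad_stim <- which(!df$stimulus %in% c("III", "V"))
  if (length(bad_stim) > 0) {
    stop(sprintf("unknown stimulus code '%s' in column 'stimulus' at row %d",
                 df$stimulus[bad_stim[1]], bad_stim[1]), call. = FALSE)
  }
  bad_eye <- which(!df$eye %in% c("right", "left"))
  if (length(bad_eye) > 0) {
    stop(sprintf("unknown eye code '%s' in column 'eye' at row %d",
                 df$eye[bad_eye[1]], bad_eye[1]), call. = FALSE)
  }
  check_range <- function(cc, lo, hi) {
    v <- df[[cc]]
    bad <- which(is.na(v) | v < lo | v > hi)
    if (length(bad) > 0) {
      stop(sprintf("value out of range in column '%s' at row %d", cc, bad[1]),
           call. = FALSE)
    }
  }
  check_range("age", 1e-9, 150)
  check_range("fp_rate", 0, 1)
  for (cc in loc_cols()) check_range(cc, 0, 60)
  class(df) <- unique(c("vf_table", class(df)))
  df
}

#' Write a visual-field table to CSV
#'
#' @param x A `vf_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vf_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the n x 52 sensitivity matrix
#'
#' @param x A `vf_table`.
#' @return Numeric matrix, one row per field.
#' @export
vf_matrix <- function(x) {
  as.matrix(as.data.frame(x)[, loc_cols(), drop = FALSE])
}

#' Mirror left-eye fields onto right-eye orientation
#'
#' Visual-field patterns pool across eyes only after anatomic alignment:
#' a left eye's field is the mirror image of a right eye's about the
#' vertical midline. This reorders each left-eye row of the table by the
#' mirror permutation (a pure index permutation; no value changes) and
#' marks the table canonicalized. Right-eye rows pass through unchanged,
#' and eye labels are preserved. Applying the mirror twice restores the
#' original ordering.
#'
#' Mirroring can be skipped (`mirror = FALSE`) for analyses that keep eyes
#' in native orientation; downstream functions only require the flag.
#'
#' @param x A `vf_table`.
#' @param grid Grid convention.
#' @param mirror If `FALSE`, only set the canonicalized flag.
#' @return The table, with attribute `canonicalized = TRUE`.
#' @export
canonicalize_eye <- function(x, grid = vf_grid(), mirror = TRUE) {
  if (mirror && any(x$eye == "left")) {
    p <- mirror_permutation(grid)
    m <- vf_matrix(x)
    left <- x$eye == "left"
    m[left, ] <- m[left, p, drop = FALSE]
    x[, loc_cols()] <- m
  }
  attr(x, "canonicalized") <- TRUE
  x
}

is_canonicalized <- function(x) isTRUE(attr(x, "canonicalized"))
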