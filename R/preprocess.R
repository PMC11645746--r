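#' Censoring and quality-exclusion configuration
#'
#' Sensitivities measured far below the dynamic range are noise-dominated:
#' the signal-to-noise ratio of standard automated perimetry collapses at
#' low dB, and retest variability there obscures pattern structure.
#' Censoring replaces every sensitivity *below* a stimulus-specific
#' threshold by the threshold itself (values exactly at the threshold are
#' untouched). The defaults, 21 dB for size III and 24 dB for size V, are
#' the thresholds that equate the two stimuli in moderate-to-severe optic
#' neuropathy. Fields whose false-positive rate exceeds `fp_max` are
#' excluded because spuriously high sensitivities inflate positive total
#' deviations and archetypal analysis builds its patterns from the edge of
#' the data cloud.
#'
#' @param threshold_III Censoring threshold for size III (dB).
#' @param threshold_V Censoring threshold for size V (dB).
#' @param fp_max Maximum tolerated false-positive rate (strictly greater
#'   values are excluded).
#' @return A `censoring_config` list.
#' @export
censoring_config <- function(threshold_III = 21, threshold_V = 24, fp_max = 0.20) {
  stopifnot(threshold_III >= 0, threshold_V >= 0, fp_max > 0, fp_max <= 1)
  structure(list(threshold_III = threshold_III, threshold_V = threshold_V,
                 fp_max = fp_max),
            class = "censoring_config")
}

censor_threshold <- function(cfg, stimulus) {
  ifelse(stimulus == "V", cfg$threshold_V, cfg$threshold_III)
}

#' Censor raw sensitivities at the stimulus threshold
#'
#' Each sensitivity strictly below the threshold for its row's stimulus is
#' replaced by that threshold. The operation is idempotent and monotone.
#'
#' @param x A `vf_table`.
#' @param cfg A [censoring_config()].
#' @return The censored table, with attributes `censored = TRUE` and
#'   `censored_fraction` (overall fraction of values raised).
#' @export
censor <- function(x, cfg = censoring_config()) {
  m <- vf_matrix(x)
  thr <- censor_threshold(cfg, x$stimulus)
  tm <- matrix(thr, nrow = nrow(m), ncol = ncol(m))
  below <- m < tm
  m[below] <- tm[below]
  x[, loc_cols()] <- m
  attr(x, "censored") <- TRUE
  attr(x, "censored_fraction") <- mean(below)
  x
}

#' Exclude unreliable fields by false-positive rate
#'
#' @param x A `vf_table`.
#' @param cfg A [censoring_config()].
#' @return List with `kept`, `excluded` (both `vf_table`s), `n_kept`,
#'   `n_excluded`.
#' @export
quality_filter <- function(x, cfg = censoring_config()) {
  drop <- x$fp_rate > cfg$fp_max
  keep_attrs <- function(y) {
    for (a in c("canonicalized", "censored")) attr(y, a) <- attr(x, a)
    y
  }
  list(kept = keep_attrs(x[!drop, , drop = FALSE]),
       excluded = keep_attrs(x[drop, , drop = FALSE]),
       n_kept = sum(!drop), n_excluded = sum(drop))
}

#' Age-standardize censored sensitivities to total deviation
#'
#' Total deviation (TD) at a location is the measured sensitivity minus
#' the age-matched normal sensitivity there; it can be positive. The
#' pipeline order is fixed: censor first, then convert, so `to_td()`
#' refuses an uncensored table unless `allow_uncensored = TRUE` (the
#' uncensored pathway exists for comparison analyses). Left-eye rows must
#' have been canonicalized first, because the normative model is quoted in
#' right-eye orientation.
#'
#' @param x A censored `vf_table`.
#' @param normative A `normative_model`.
#' @param allow_uncensored Permit conversion of uncensored sensitivities.
#' @return A `td_table`: data frame with `patient_id`, `eye`, `stimulus`
#'   and `td_01` .. `td_52` (dB).
#' @export
to_td <- function(x, normative = default_normative(), allow_uncensored = FALSE) {
  if (!isTRUE(attr(x, "censored")) && !allow_uncensored) {
    stop("input has not been censored; run censor() first or set ",
         "allow_uncensored = TRUE for the uncensored pathway", call. = FALSE)
  }
  if (any(x$eye == "left") && !is_canonicalized(x)) {
    stop("left-eye rows present but table not canonicalized; ",
         "run canonicalize_eye() first", call. = FALSE)
  }
  m <- vf_matrix(x)
  norm_m <- t(vapply(seq_len(nrow(x)),
                     function(i) normative_values(normative, x$stimulus[i], x$age[i]),
                     numeric(52)))
  td <- m - norm_m
  out <- data.frame(patient_id = x$patient_id, eye = x$eye,
                    stimulus = x$stimulus, stringsAsFactors = FALSE)
  out[, td_cols()] <- td
  class(out) <- unique(c("td_table", class(out)))
  attr(out, "censored") <- isTRUE(attr(x, "censored"))
  out
}

#' Extract the n x 52 total-deviation matrix
#'
#' @param x A `td_table`.
#' @return Numeric matrix, one row per field.
#' @export
td_matrix <- function(x) {
  as.matrix(as.data.frame(x)[, td_cols(), drop = FALSE])
}

#' Full preprocessing chain
#'
#' Canonicalize eyes, drop high false-positive fields, censor, and convert
#' to total deviation.
#'
#' @param x A `vf_table`.
#' @param normative A `normative_model`.
#' @param cfg A [censoring_config()].
#' @param censor_values If `FALSE`, skip censoring (uncensored pathway).
#' @param mirror_left Mirror left eyes to right-eye orientation.
#' @return List with `td` (a `td_table`), `n_kept`, `n_excluded`,
#'   `censored_fraction` (NA when censoring is skipped).
#' @export
preprocess_vf <- function(x, normative = default_normative(),
                          cfg = censoring_config(), censor_values = TRUE,
                          mirror_left = TRUE) {
  x <- canonicalize_eye(x, mirror = mirror_left)
  qf <- quality_filter(x, cfg)
  kept <- qf$kept
  frac <- NA_real_
  if (censor_values) {
    kept <- censor(kept, cfg)
    frac <- attr(kept, "censored_fraction")
  }
  td <- to_td(kept, normative, allow_uncensored = !censor_values)
  list(td = td, n_kept = qf$n_kept, n_excluded = qf$n_excluded,
       censored_fraction = frac)
}
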