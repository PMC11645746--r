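#' Parametric normative model of normal sensitivity
#'
#' Total deviation requires, for every grid location and stimulus size, the
#' sensitivity an age-matched healthy eye would show. Proprietary normative
#' databases are not redistributable, so the package uses a declared
#' parametric form: per stimulus and location, an intercept (dB at the
#' reference age) plus a linear age slope (dB/year, typically negative).
#'
#' `default_normative()` builds a synthetic model with the familiar shape
#' of normal hill-of-vision data: sensitivity declines with eccentricity
#' and with age, and the larger size V stimulus sits several dB higher
#' with a flatter eccentricity profile than size III.
#'
#' @param grid Grid convention.
#' @param reference_age Age (years) at which intercepts are quoted.
#' @param age_support Ages for which the model is considered valid.
#' @return A `normative_model`: list with elements `III` and `V` (data
#'   frames of 52 intercepts and slopes), `reference_age`, `age_support`.
#' @examples
#' nm <- default_normative()
#' head(normative_values(nm, "III", age = 65))
#' @export
default_normative <- function(grid = vf_grid(), reference_age = 50,
                              age_support = c(18, 95)) {
  ecc <- sqrt(grid$x^2 + grid$y^2)
  model <- list(
    III = data.frame(intercept = 34 - 0.25 * ecc, slope = rep(-0.065, nrow(grid))),
    V   = data.frame(intercept = 36.5 - 0.18 * ecc, slope = rep(-0.055, nrow(grid))),
    reference_age = reference_age,
    age_support = age_support
  )
  class(model) <- "normative_model"
  model
}

#' Evaluate a normative model
#'
#' @param model A `normative_model`.
#' @param stimulus `"III"` or `"V"`.
#' @param age Age in years; must lie within the model's support.
#' @return Numeric vector of 52 normal sensitivities (dB).
#' @export
normative_values <- function(model, stimulus, age) {
  stimulus <- match.arg(stimulus, c("III", "V"))
  if (age < model$age_support[1] || age > model$age_support[2]) {
    stop(sprintf("age %.1f outside normative model support [%g, %g]",
                 age, model$age_support[1], model$age_support[2]), call. = FALSE)
  }
  tab <- model[[stimulus]]
  tab$intercept + tab$slope * (age - model$reference_age)
}

#' Write / read a normative model as JSON
#'
#' The JSON layout is
#' `{"III": [{"intercept": .., "slope": ..} x 52], "V": [...],
#'  "reference_age": 50, "age_support": [18, 95]}`.
#'
#' @param model A `normative_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_normative()` returns the model.
#' @export
write_normative <- function(model, path) {
  obj <- list(III = model$III, V = model$V,
              reference_age = model$reference_age,
              age_support = model$age_support)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(III = as.data.frame(obj$III), V = as.data.frame(obj$V),
                reference_age = obj$reference_age,
                age_support = as.numeric(obj$age_support))
  stopifnot(nrow(model$III) == 52, nrow(model$V) == 52)
  class(model) <- "normative_model"
  model
}
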