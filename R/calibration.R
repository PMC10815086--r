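#' Summarize a calibrant measurement into a calibration point
#'
#' Reduces the binding events of a calibration-standard movie (or several
#' movies of the same standard, e.g. measured at the start and end of a run
#' sequence and merged) to a single contrast location paired with the
#' standard's reference mass. The location is the median by default — robust
#' against the stray aggregates and debris a real standard carries — with the
#' mean available as an option.
#'
#' @param events An [event_set()], or a list of event sets to merge.
#' @param reference_mass Known mass of the standard in kDa.
#' @param location `"median"` (default) or `"mean"`.
#' @param min_events Minimum number of binding events required (default 100).
#' @return An object of class `calibration_point`: a list with `name`,
#'   `reference_mass`, `mean_contrast`, `n_events`.
#' @export
summarize_calibrant <- function(events, reference_mass,
                                location = c("median", "mean"),
                                min_events = 100L) {
  location <- match.arg(location)
  if (inherits(events, "event_set")) events <- list(events)
  stopifnot(all(vapply(events, inherits, logical(1), "event_set")))
  contrasts <- unlist(lapply(events, function(e) binding_events(e)$contrast))
  if (length(contrasts) < min_events) {
    stop("calibrant has ", length(contrasts), " binding events; at least ",
         min_events, " are required", call. = FALSE)
  }
  loc <- if (location == "median") stats::median(contrasts) else mean(contrasts)
  structure(
    list(name = events[[1]]$sample_id, reference_mass = reference_mass,
         mean_contrast = loc, n_events = length(contrasts)),
    class = "calibration_point"
  )
}

#' The zero calibration point
#'
#' At the zero point both the molar mass and the ratiometric contrast are
#' zero; it can replace a physical low-mass standard in the calibration.
#'
#' @return A `calibration_point` with mass, contrast and event count all 0.
#' @export
zero_point <- function() {
  structure(list(name = "zero", reference_mass = 0, mean_contrast = 0,
                 n_events = 0L),
            class = "calibration_point")
}

#' Fit a linear contrast-to-mass calibration model
#'
#' Ordinary least squares of reference mass on mean contrast over the given
#' calibration points. Three variants are supported, named after the point
#' sets they expect:
#'
#' * `tg_aav9e` — two physical standards (thyroglobulin and empty AAV9);
#'   exact two-point interpolation, R^2 = 1.
#' * `zero_aav9e` — the zero point plus empty AAV9; a line through the
#'   origin, again exact.
#' * `zero_tg_aav9e` — all three points, fitted by unweighted OLS with the
#'   zero point entering as an ordinary datum; R^2 < 1 unless collinear.
#'
#' @param points List of `calibration_point`s (order irrelevant). The zero
#'   point, where a variant requires it, may be included or is added
#'   automatically.
#' @param variant Calibration variant; see above.
#' @return An object of class `calibration_model` with fields `slope`
#'   (kDa per contrast unit), `intercept` (kDa), `r_squared`, `points`,
#'   `residuals` and `variant`.
#' @export
#' @examples
#' pts <- list(
#'   structure(list(name = "TG", reference_mass = 670, mean_contrast = 0.0335,
#'                  n_events = 500L), class = "calibration_point"),
#'   structure(list(name = "AAV9e", reference_mass = 3740,
#'                  mean_contrast = 0.187, n_events = 800L),
#'             class = "calibration_point"))
#' fit_calibration(pts, "tg_aav9e")
fit_calibration <- function(points,
                            variant = c("zero_aav9e", "tg_aav9e",
                                        "zero_tg_aav9e")) {
  variant <- match.arg(variant)
  stopifnot(all(vapply(points, inherits, logical(1), "calibration_point")))
  if (variant %in% c("zero_aav9e", "zero_tg_aav9e")) {
    has_zero <- any(vapply(points, function(p)
      p$reference_mass == 0 && p$mean_contrast == 0, logical(1)))
    if (!has_zero) points <- c(list(zero_point()), points)
  }
  n_expected <- switch(variant, tg_aav9e = 2L, zero_aav9e = 2L,
                       zero_tg_aav9e = 3L)
  if (length(points) != n_expected) {
    stop("variant '", variant, "' expects ", n_expected,
         " calibration points, got ", length(points), call. = FALSE)
  }
  x <- vapply(points, `[[`, numeric(1), "mean_contrast")
  y <- vapply(points, `[[`, numeric(1), "reference_mass")
  if (anyDuplicated(x)) {
    stop("duplicate contrast values make the calibration fit singular",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) {
    stop("calibration slope is not positive; check calibrant assignment",
         call. = FALSE)
  }
  fitted_mass <- intercept + slope * x
  resid <- y - fitted_mass
  r2 <- if (length(points) == 2L) {
    1  # exact interpolation convention
  } else {
    1 - sum(resid^2) / sum((y - mean(y))^2)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         points = points, residuals = resid, variant = variant),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model %s> mass = %.6g * contrast + %.6g kDa, R^2 = %.6g\n",
              x$variant, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Predict mass from contrast
#'
#' @param model A `calibration_model`.
#' @param contrast Numeric vector of ratiometric contrasts.
#' @return Masses in kDa.
#' @export
predict_mass <- function(model, contrast) {
  stopifnot(inherits(model, "calibration_model"))
  model$slope * contrast + model$intercept
}

#' Annotate an event set with calibrated masses
#'
#' Adds a `mass_kDa` column: `slope * contrast + intercept` for binding
#' events; unbinding events pass through with `NA` mass. Negative masses
#' (contrasts below a nonzero intercept) are retained rather than clipped so
#' downstream QC can flag a miscalibration.
#'
#' @param model A `calibration_model`.
#' @param es An [event_set()].
#' @return The event set with a `mass_kDa` column.
#' @export
apply_calibration <- function(model, es) {
  stopifnot(inherits(model, "calibration_model"), inherits(es, "event_set"))
  es$events$mass_kDa <- ifelse(
    es$events$event_type == "binding",
    predict_mass(model, es$events$contrast),
    NA_real_
  )
  es$calibration <- model
  es
}
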