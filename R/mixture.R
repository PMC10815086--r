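#' Mixture specification for a simulated sample
#'
#' Describes the particle population of a simulated mass-photometry sample as
#' a set of mass components (one row per class), a background fraction of
#' low-mass contaminant events (crude-extract emulation), and optionally a
#' payload geometry used to draw partially-filled capsids with a per-event
#' uniform fill fraction instead of a fixed Gaussian mean.
#'
#' @param components A data frame with columns `class_label`, `mass_kDa`,
#'   `sd_kDa` and `proportion`. Proportions must sum to 1 (within 1e-9) and
#'   masses must be strictly increasing down the rows.
#' @param background_fraction Fraction of all particle events that are
#'   low-mass contaminants rather than capsids (default 0).
#' @param shell_mass_kDa,payload_mass_kDa Optional capsid geometry. When both
#'   are given and a `"partial"` class is present, partial events are drawn
#'   as `shell + U(fill_range) * payload` (plus the class mass jitter)
#'   rather than from a fixed class mean.
#' @param partial_fill_range Numeric length-2: range of the uniform fill
#'   fraction for partially-filled capsids (default `c(0.2, 0.8)`).
#'
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, background_fraction = 0,
                         shell_mass_kDa = NULL, payload_mass_kDa = NULL,
                         partial_fill_range = c(0.2, 0.8)) {
  components <- tibble::as_tibble(components)
  need <- c("class_label", "mass_kDa", "sd_kDa", "proportion")
  if (!all(need %in% names(components))) {
    stop("`components` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  p <- components$proportion
  if (any(p < 0 | p > 1)) {
    stop("component proportions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("component proportions must sum to 1 (got ", sum(p), ")",
         call. = FALSE)
  }
  if (any(diff(components$mass_kDa) <= 0)) {
    stop("component masses must be strictly increasing", call. = FALSE)
  }
  if (any(components$sd_kDa <= 0)) {
    stop("component mass SDs must be > 0", call. = FALSE)
  }
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("`background_fraction` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(components = components,
         background_fraction = background_fraction,
         shell_mass_kDa = shell_mass_kDa,
         payload_mass_kDa = payload_mass_kDa,
         partial_fill_range = partial_fill_range),
    class = "mixture_spec"
  )
}

#' Four-class AAV mixture from a capsid model
#'
#' Convenience constructor building an empty/partial/full/overfull
#' [mixture_spec()] whose class masses derive from a [capsid_model()]
#' (empty = shell, full = shell + payload, overfull = shell + 1.3 payload;
#' partial drawn with a uniform fill fraction at simulation time).
#'
#' @param proportions Named or ordered numeric of length 4
#'   (empty, partial, full, overfull); must sum to 1.
#' @param model A [capsid_model()].
#' @param sd_kDa Mass SD per class in kDa (recycled; default 70).
#' @param background_fraction See [mixture_spec()].
#' @return A `mixture_spec`.
#' @export
aav_mixture <- function(proportions, model = capsid_model(), sd_kDa = 70,
                        background_fraction = 0) {
  if (length(proportions) != 4L) {
    stop("`proportions` must have length 4 (empty, partial, full, overfull)",
         call. = FALSE)
  }
  proportions <- unname(proportions)
  masses <- vapply(aav_classes, function(cl) capsid_mass(model, cl),
                   numeric(1))
  mixture_spec(
    tibble::tibble(
      class_label = aav_classes,
      mass_kDa = unname(masses),
      sd_kDa = rep_len(sd_kDa, 4L),
      proportion = proportions
    ),
    background_fraction = background_fraction,
    shell_mass_kDa = shell_mass(model),
    payload_mass_kDa = payload_mass(model)
  )
}

#' Acquisition configuration for a simulated movie
#'
#' Collects the instrument-side parameters of one simulated measurement:
#' movie duration, sample concentration, the landing factor kappa (expected
#' binding events per second per unit concentration), the focus/operation
#' mode, and the parameters of the generating contrast-mass line.
#'
#' The expected binding-event count of a movie is
#' `kappa * concentration * duration * mode_rate_multiplier`. The multiplier
#' is 1 for all modes except `buffer_dilution_auto_unmixed`, where the robot
#' dispenses sample into buffer without mixing; that mode defaults to a 1.6x
#' count-rate inflation with doubled Poisson dispersion (a synthetic choice;
#' the effect is only reported qualitatively for the instrument).
#'
#' @param duration Movie length in seconds (default 60).
#' @param concentration Capsid concentration in cp/mL.
#' @param kappa Landing factor, events/s per (cp/mL). Default 1e-9.
#' @param mode One of `"buffer_free_manual"`, `"buffer_free_auto"`,
#'   `"buffer_dilution_manual"`, `"buffer_dilution_auto_unmixed"`.
#' @param mode_rate_multiplier Count-rate multiplier; must be 1 for
#'   buffer-free modes. `NULL` picks the mode default.
#' @param count_dispersion Ratio of count variance to mean; 1 is Poisson.
#'   `NULL` picks the mode default (2 for the unmixed automated mode).
#' @param replicate_count Number of replicates a driver should simulate.
#' @param contrast_noise_sd SD of additive contrast noise per event.
#' @param true_slope,true_intercept Generating contrast-to-mass line
#'   (kDa per contrast unit, kDa); events are simulated by inverting it.
#' @param unbinding_fraction Expected unbinding events per binding event.
#' @param seed Integer seed; replicate i uses `seed + i`.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(duration = 60, concentration = 1e11,
                               kappa = 1e-9,
                               mode = c("buffer_free_manual",
                                        "buffer_free_auto",
                                        "buffer_dilution_manual",
                                        "buffer_dilution_auto_unmixed"),
                               mode_rate_multiplier = NULL,
                               count_dispersion = NULL,
                               replicate_count = 1L,
                               contrast_noise_sd = 2e-3,
                               true_slope = 2e4, true_intercept = 0,
                               unbinding_fraction = 0.1,
                               seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(mode_rate_multiplier)) {
    mode_rate_multiplier <- if (mode == "buffer_dilution_auto_unmixed") 1.6 else 1
  }
  if (is.null(count_dispersion)) {
    count_dispersion <- if (mode == "buffer_dilution_auto_unmixed") 2 else 1
  }
  if (duration <= 0) stop("`duration` must be > 0 s", call. = FALSE)
  if (concentration < 0) stop("`concentration` must be >= 0", call. = FALSE)
  if (kappa <= 0) stop("`kappa` must be > 0", call. = FALSE)
  if (mode_rate_multiplier < 1) {
    stop("`mode_rate_multiplier` must be >= 1", call. = FALSE)
  }
  if (startsWith(mode, "buffer_free") && mode_rate_multiplier != 1) {
    stop("buffer-free modes have no count-rate inflation: multiplier must be 1",
         call. = FALSE)
  }
  if (count_dispersion < 1) stop("`count_dispersion` must be >= 1", call. = FALSE)
  if (true_slope <= 0) stop("`true_slope` must be > 0", call. = FALSE)
  if (contrast_noise_sd < 0) stop("`contrast_noise_sd` must be >= 0", call. = FALSE)
  if (unbinding_fraction < 0) stop("`unbinding_fraction` must be >= 0", call. = FALSE)
  structure(
    list(duration = duration, concentration = concentration, kappa = kappa,
         mode = mode, mode_rate_multiplier = mode_rate_multiplier,
         count_dispersion = count_dispersion,
         replicate_count = as.integer(replicate_count),
         contrast_noise_sd = contrast_noise_sd,
         true_slope = true_slope, true_intercept = true_intercept,
         unbinding_fraction = unbinding_fraction,
         seed = as.integer(seed)),
    class = "acquisition_config"
  )
}

#' Named simulation presets
#'
#' Returns a fully-populated `(mixture, acquisition)` pair for one of the
#' documented study conditions:
#'
#' * `reference_aav9` — purified AAV9 reference sample: ~33% empty, 6%
#'   partially filled, 52% full, 8% overfull.
#' * `harvest_mix_a` — AAV9 purified from a crude harvest produced with
#'   transfection reagent A: full-particle proportion 11.2%, large
#'   partially-filled fraction, nonzero low-mass background.
#' * `harvest_mix_b` — transfection reagent B harvest: roughly threefold the
#'   filled fraction of mix A. Component values are illustrative — only the
#'   threefold filled-fraction increase is anchored.
#' * `aav8_extract` — AAV8 magnetic-bead extract showing two dominant
#'   fractions (empty and full); illustrative composition.
#' * `calibrant_tg` — thyroglobulin calibration standard, 670 kDa.
#' * `calibrant_aav9e` — "empty" AAV9 calibration standard, 3740 kDa,
#'   measured at ~3.3e11 cp/mL.
#' * `mec_reference` / `mfc_reference` — mostly-empty / mostly-full capsid
#'   reference samples used to place the subpopulation mass gates
#'   (synthetic compositions: 95% empty resp. 90% full).
#'
#' @param name Preset name.
#' @param seed Seed stored in the returned acquisition config.
#' @param model Capsid model used to derive class masses.
#' @return A list with elements `mixture` ([mixture_spec()]) and
#'   `acquisition` ([acquisition_config()]).
#' @export
#' @examples
#' p <- preset("reference_aav9", seed = 1)
#' p$mixture$components
preset <- function(name, seed = 1L, model = capsid_model()) {
  valid <- c("reference_aav9", "harvest_mix_a", "harvest_mix_b",
             "aav8_extract", "calibrant_tg", "calibrant_aav9e",
             "mec_reference", "mfc_reference")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown preset ", deparse(name), "; valid presets: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  single <- function(label, mass, sd) {
    mixture_spec(tibble::tibble(class_label = label, mass_kDa = mass,
                                sd_kDa = sd, proportion = 1))
  }
  mixture <- switch(
    name,
    # printed as ~33/6/52/8 percent, which sums to 99; normalized here
    reference_aav9 = aav_mixture(c(33, 6, 52, 8) / 99, model = model),
    harvest_mix_a = aav_mixture(c(0.55, 0.28, 0.112, 0.058), model = model,
                                background_fraction = 0.15),
    harvest_mix_b = aav_mixture(c(0.40, 0.194, 0.336, 0.07), model = model,
                                background_fraction = 0.15),
    aav8_extract = aav_mixture(c(0.55, 0.05, 0.37, 0.03), model = model,
                               background_fraction = 0.20),
    calibrant_tg = single("calibrant", 670, 30),
    calibrant_aav9e = single("calibrant", shell_mass(model), 70),
    mec_reference = aav_mixture(c(0.95, 0.03, 0.015, 0.005), model = model),
    mfc_reference = aav_mixture(c(0.05, 0.03, 0.90, 0.02), model = model)
  )
  concentration <- switch(name, calibrant_aav9e = 3.3e11, 1e11)
  acq <- acquisition_config(concentration = concentration, seed = seed)
  list(mixture = mixture, acquisition = acq)
}
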