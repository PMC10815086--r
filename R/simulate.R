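#' Construct an event set
#'
#' An event set is one movie's worth of detected single-particle events plus
#' its metadata. Events are stored as a tibble with columns `time_s`,
#' `contrast` and `event_type` (`"binding"` or `"unbinding"`); simulated sets
#' additionally carry a `true_class` column (the generating class label) that
#' survives in memory but is not part of the on-disk event CSV.
#'
#' @param events Tibble of events, sorted by time.
#' @param sample_id Sample identifier.
#' @param dilution_factor Dilution applied before measurement (>= 1).
#' @param acquisition Optional [acquisition_config()].
#' @param truth Optional [mixture_spec()] ground truth.
#' @return An object of class `event_set`.
#' @export
event_set <- function(events, sample_id = "sample", dilution_factor = 1,
                      acquisition = NULL, truth = NULL) {
  events <- tibble::as_tibble(events)
  need <- c("time_s", "contrast", "event_type")
  if (!all(need %in% names(events))) {
    stop("`events` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(events$time_s)) {
    events <- events[order(events$time_s), ]
  }
  if (!all(events$event_type %in% c("binding", "unbinding"))) {
    stop("`event_type` must be 'binding' or 'unbinding'", call. = FALSE)
  }
  if (dilution_factor < 1) stop("`dilution_factor` must be >= 1", call. = FALSE)
  structure(
    list(events = events, sample_id = sample_id,
         dilution_factor = dilution_factor,
         acquisition = acquisition, truth = truth),
    class = "event_set"
  )
}

#' @export
print.event_set <- function(x, ...) {
  nb <- sum(x$events$event_type == "binding")
  cat(sprintf("<event_set '%s'> %d events (%d binding), dilution %g\n",
              x$sample_id, nrow(x$events), nb, x$dilution_factor))
  invisible(x)
}

#' Binding events of an event set
#'
#' Only binding events enter the mass analysis and the binding count rate;
#' unbinding events are retained in the record but excluded here.
#'
#' @param es An `event_set`.
#' @return Tibble of binding events.
#' @export
binding_events <- function(es) {
  stopifnot(inherits(es, "event_set"))
  es$events[es$events$event_type == "binding", ]
}

# draw one movie's binding-event count: Poisson, or gamma-mixed Poisson
# (negative binomial) when the mode inflates dispersion above 1
draw_event_count <- function(mean_count, dispersion) {
  if (mean_count == 0) return(0L)
  if (dispersion <= 1) {
    stats::rpois(1L, mean_count)
  } else {
    # var = mu * dispersion  =>  size = mu / (dispersion - 1)
    stats::rnbinom(1L, mu = mean_count,
                   size = mean_count / (dispersion - 1))
  }
}

# draw particle masses (kDa) for a vector of class labels
draw_masses <- function(labels, mixture) {
  comp <- mixture$components
  idx <- match(labels, comp$class_label)
  mass <- rep(NA_real_, length(labels))
  known <- !is.na(idx)
  mass[known] <- stats::rnorm(sum(known), comp$mass_kDa[idx[known]],
                              comp$sd_kDa[idx[known]])
  uniform_partial <- !is.null(mixture$shell_mass_kDa) &&
    !is.null(mixture$payload_mass_kDa)
  if (uniform_partial) {
    ip <- which(labels == "partial")
    if (length(ip)) {
      fill <- stats::runif(length(ip), mixture$partial_fill_range[1],
                           mixture$partial_fill_range[2])
      sd_p <- comp$sd_kDa[match("partial", comp$class_label)]
      mass[ip] <- mixture$shell_mass_kDa +
        fill * mixture$payload_mass_kDa +
        stats::rnorm(length(ip), 0, sd_p)
    }
  }
  bg <- which(labels == "background")
  if (length(bg)) {
    # low-mass contaminants in crude extracts: mean 600 kDa, sd 300 kDa
    mass[bg] <- stats::rgamma(length(bg), shape = 4, scale = 150)
  }
  mass
}

#' Simulate one mass-photometry movie
#'
#' Draws a binding-event count from a Poisson law with mean
#' `kappa * concentration * duration * mode_rate_multiplier` (over-dispersed
#' for the unmixed automated buffer-dilution mode), assigns each event a
#' class from the mixture proportions (or background), draws its mass with
#' Gaussian jitter, and converts mass to ratiometric contrast by inverting
#' the generating line `mass = true_slope * contrast + true_intercept`, with
#' additive contrast noise. Unbinding events are generated as a binomial
#' fraction of the binding count and carry contrasts drawn from the same
#' mixture; they take no part in mass or rate analysis. Contrasts are stored
#' as positive magnitudes.
#'
#' @param mixture A [mixture_spec()].
#' @param acq An [acquisition_config()]; `acq$seed` seeds the draw.
#' @param sample_id,dilution_factor Metadata for the returned [event_set()].
#' @param n_events Optional exact binding-event count, bypassing the Poisson
#'   draw — used for fixed-size experiments; `NULL` (default) draws it.
#' @return An [event_set()] with `true_class` annotations and the mixture
#'   stored as `truth`.
#' @export
#' @examples
#' p <- preset("reference_aav9", seed = 42)
#' es <- simulate_sample(p$mixture, p$acquisition)
#' es
simulate_sample <- function(mixture, acq, sample_id = "sim",
                            dilution_factor = 1, n_events = NULL) {
  stopifnot(inherits(mixture, "mixture_spec"),
            inherits(acq, "acquisition_config"))
  set.seed(acq$seed)
  mean_count <- acq$kappa * acq$concentration * acq$duration *
    acq$mode_rate_multiplier
  n <- if (is.null(n_events)) {
    draw_event_count(mean_count, acq$count_dispersion)
  } else {
    as.integer(n_events)
  }

  comp <- mixture$components
  labels <- character(0)
  if (n > 0) {
    pool <- c(comp$class_label, "background")
    prob <- c((1 - mixture$background_fraction) * comp$proportion,
              mixture$background_fraction)
    labels <- sample(pool, n, replace = TRUE, prob = prob)
  }
  mass <- draw_masses(labels, mixture)
  contrast <- (mass - acq$true_intercept) / acq$true_slope +
    stats::rnorm(n, 0, acq$contrast_noise_sd)
  contrast <- abs(contrast)  # stored as magnitudes

  n_unbind <- if (n > 0) stats::rbinom(1L, n, min(acq$unbinding_fraction, 1)) else 0L
  if (n_unbind > 0) {
    ulabels <- sample(comp$class_label, n_unbind, replace = TRUE,
                      prob = comp$proportion)
    umass <- draw_masses(ulabels, mixture)
    ucontrast <- abs((umass - acq$true_intercept) / acq$true_slope +
                       stats::rnorm(n_unbind, 0, acq$contrast_noise_sd))
  }

  events <- tibble::tibble(
    time_s = stats::runif(n, 0, acq$duration),
    contrast = contrast,
    event_type = rep("binding", n),
    true_class = labels
  )
  if (n_unbind > 0) {
    events <- dplyr::bind_rows(events, tibble::tibble(
      time_s = stats::runif(n_unbind, 0, acq$duration),
      contrast = ucontrast,
      event_type = "unbinding",
      true_class = ulabels
    ))
  }
  events <- events[order(events$time_s), ]
  event_set(events, sample_id = sample_id,
            dilution_factor = dilution_factor,
            acquisition = acq, truth = mixture)
}

#' Simulate replicate movies
#'
#' Replicate `i` is simulated with seed `acq$seed + i`, so a single global
#' seed expands deterministically into per-replicate child seeds.
#'
#' @inheritParams simulate_sample
#' @param n_replicates Number of replicate movies.
#' @return List of [event_set()]s, named `<sample_id>_r1`, ...
#' @export
simulate_replicates <- function(mixture, acq, n_replicates = 5L,
                                sample_id = "sim", dilution_factor = 1,
                                n_events = NULL) {
  lapply(seq_len(n_replicates), function(i) {
    acq_i <- acq
    acq_i$seed <- acq$seed + i
    simulate_sample(mixture, acq_i,
                    sample_id = sprintf("%s_r%d", sample_id, i),
                    dilution_factor = dilution_factor, n_events = n_events)
  })
}
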