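#' Quantify subpopulation composition of a calibrated sample
#'
#' Classifies every calibrated binding event into the gate windows and
#' reports class percentages relative to the events at or above the lower
#' cutoff (sub-capsid background is excluded from the denominator and
#' reported separately as a QC fraction). Capsid masses come from the fitted
#' Gaussian components where available (empty and full); the partially
#' filled and overfull classes, which rarely show a resolvable peak, are
#' reported as window event-medians. The payload (transgene) mass is the
#' difference of the full and empty peak means, reported as `NA` — absent,
#' not zero — if either peak is missing.
#'
#' Percentages can alternatively be computed from the fitted Gaussian areas
#' (`percentages_from = "areas"`); this requires a fitted component in every
#' class and agrees with event counting on well-separated mixtures.
#'
#' @param es Mass-annotated [event_set()].
#' @param gates A [subpop_gates()].
#' @param components Optional result of [fit_components()]; fitted from the
#'   event histogram when `NULL`.
#' @param bin_width Bin width used when `components` must be fitted.
#' @param min_events Per-window fit threshold, see [fit_components()].
#' @param percentages_from `"counts"` (default) or `"areas"`.
#' @return Object of class `composition_result`: percentages per class,
#'   component fits, empty/full/partial/overfull masses, payload mass,
#'   `n_events_used`, `background_fraction`, and the gates used.
#' @export
quantify <- function(es, gates, components = NULL, bin_width = 40,
                     min_events = 50L,
                     percentages_from = c("counts", "areas")) {
  percentages_from <- match.arg(percentages_from)
  stopifnot(inherits(es, "event_set"), inherits(gates, "subpop_gates"))
  if (!("mass_kDa" %in% names(es$events))) {
    stop("event set is not mass-annotated; run apply_calibration() first",
         call. = FALSE)
  }
  mass <- binding_events(es)$mass_kDa
  cls <- classify_mass(mass, gates)
  n_total <- length(mass)
  n_bg <- sum(cls == "background")
  n_used <- n_total - n_bg
  if (n_used == 0L) {
    stop("no events above the lower cutoff; nothing to quantify", call. = FALSE)
  }
  counts <- table(factor(cls[cls != "background"], levels = aav_classes))

  if (is.null(components)) {
    hist <- build_histogram(es, bin_width = bin_width,
                            lower_cutoff = gates$lower_cutoff)
    components <- fit_components(hist, gates, min_events = min_events)
  }

  percentages <- if (percentages_from == "counts") {
    100 * as.numeric(counts) / n_used
  } else {
    if (!all(aav_classes %in% names(components))) {
      stop("area-based percentages need a fitted component in every class",
           call. = FALSE)
    }
    areas <- vapply(components[aav_classes], function(cp)
      cp$amplitude * cp$sd * sqrt(2 * pi), numeric(1))
    100 * areas / sum(areas)
  }
  names(percentages) <- aav_classes

  comp_mean <- function(cl) {
    if (!is.null(components[[cl]])) components[[cl]]$mean else NA_real_
  }
  window_median <- function(cl) {
    m <- mass[cls == cl]
    if (length(m)) stats::median(m) else NA_real_
  }
  empty_mass <- comp_mean("empty")
  full_mass <- comp_mean("full")
  structure(
    list(sample_id = es$sample_id,
         percentages = percentages,
         components = components,
         empty_mass = empty_mass,
         full_mass = full_mass,
         partial_mass = window_median("partial"),
         overfull_mass = window_median("overfull"),
         payload_mass = full_mass - empty_mass,
         n_events_used = n_used,
         background_fraction = n_bg / n_total,
         gates = gates),
    class = "composition_result"
  )
}

#' @export
print.composition_result <- function(x, ...) {
  cat(sprintf("<composition_result '%s'> n = %d (background %.1f%%)\n",
              x$sample_id, x$n_events_used, 100 * x$background_fraction))
  cat(sprintf("  %%E/PF/F/OF: %.1f / %.1f / %.1f / %.1f\n",
              x$percentages["empty"], x$percentages["partial"],
              x$percentages["full"], x$percentages["overfull"]))
  cat(sprintf("  empty %.5g kDa, full %.5g kDa, payload %.5g kDa\n",
              x$empty_mass, x$full_mass, x$payload_mass))
  invisible(x)
}

#' One-row tibble summary of a composition result
#'
#' @param result A `composition_result`.
#' @return Tibble with the results-table columns (sample id, class
#'   percentages, masses, event count, background fraction).
#' @export
composition_row <- function(result) {
  stopifnot(inherits(result, "composition_result"))
  tibble::tibble(
    sample_id = result$sample_id,
    pct_empty = unname(result$percentages["empty"]),
    pct_partial = unname(result$percentages["partial"]),
    pct_full = unname(result$percentages["full"]),
    pct_overfull = unname(result$percentages["overfull"]),
    empty_mass_kDa = result$empty_mass,
    full_mass_kDa = result$full_mass,
    payload_mass_kDa = result$payload_mass,
    n_events = result$n_events_used,
    background_fraction = result$background_fraction
  )
}

#' Replicate statistics over composition results
#'
#' Per-quantity mean, standard deviation (n - 1 denominator) and relative
#' standard deviation (RSD, 100 * sd / mean) across replicate measurements
#' of the same sample. RSD is `NA` where the mean is zero.
#'
#' @param results List of `composition_result`s (>= 2).
#' @return Object of class `replicate_stats`: a tibble `stats` with columns
#'   `quantity`, `mean`, `sd`, `rsd`, plus the per-replicate table.
#' @export
replicate_stats <- function(results) {
  if (length(results) < 2L) {
    stop("replicate statistics need at least 2 replicates, got ",
         length(results), call. = FALSE)
  }
  stopifnot(all(vapply(results, inherits, logical(1), "composition_result")))
  tbl <- dplyr::bind_rows(lapply(results, composition_row))
  quantities <- c("pct_empty", "pct_partial", "pct_full", "pct_overfull",
                  "empty_mass_kDa", "full_mass_kDa", "payload_mass_kDa")
  stats_tbl <- dplyr::bind_rows(lapply(quantities, function(q) {
    v <- tbl[[q]]
    m <- mean(v)
    s <- stats::sd(v)
    tibble::tibble(quantity = q, mean = m, sd = s,
                   rsd = if (isTRUE(m != 0)) 100 * s / m else NA_real_)
  }))
  structure(list(stats = stats_tbl, replicates = tbl,
                 n_replicates = length(results)),
            class = "replicate_stats")
}

#' @export
print.replicate_stats <- function(x, ...) {
  cat(sprintf("<replicate_stats> %d replicates\n", x$n_replicates))
  print(x$stats)
  invisible(x)
}
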