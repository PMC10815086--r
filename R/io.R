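#' Write / read an event CSV
#'
#' One file per movie, header `time_s,contrast,event_type`, UTF-8, `.`
#' decimal separator. Doubles are serialized at full (shortest round-trip)
#' precision, so write/read round-trips reproduce times and contrasts
#' bit-identically. Simulation-only columns (`true_class`, `mass_kDa`) are
#' not part of the format.
#'
#' @param es An [event_set()].
#' @param path File path.
#' @return `write_event_csv()` returns `path` invisibly; `read_event_csv()`
#'   returns an [event_set()].
#' @export
write_event_csv <- function(es, path) {
  stopifnot(inherits(es, "event_set"))
  # %.17g guarantees bit-exact double round trips
  lines <- c("time_s,contrast,event_type",
             sprintf("%.17g,%.17g,%s", es$events$time_s, es$events$contrast,
                     es$events$event_type))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_event_csv
#' @param sample_id,dilution_factor,acquisition Metadata for the event set
#'   (the CSV carries none).
#' @export
read_event_csv <- function(path, sample_id = basename(path),
                           dilution_factor = 1, acquisition = NULL) {
  # base read.csv parses doubles via strtod (correctly rounded), which the
  # bit-exact round-trip contract requires
  ev <- tibble::as_tibble(utils::read.csv(path, colClasses = c(
    time_s = "numeric", contrast = "numeric", event_type = "character"
  )))
  event_set(ev, sample_id = sample_id, dilution_factor = dilution_factor,
            acquisition = acquisition)
}

#' Write / read a histogram CSV
#'
#' Columns `bin_lo_kDa, bin_hi_kDa, count`.
#'
#' @param hist A `mass_histogram`.
#' @param path File path.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "mass_histogram"))
  readr::write_csv(tibble::tibble(
    bin_lo_kDa = utils::head(hist$bin_edges, -1),
    bin_hi_kDa = utils::tail(hist$bin_edges, -1),
    count = hist$counts
  ), path)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    bin_lo_kDa = readr::col_double(),
    bin_hi_kDa = readr::col_double(),
    count = readr::col_integer()
  ))
  edges <- c(tbl$bin_lo_kDa, tbl$bin_hi_kDa[nrow(tbl)])
  structure(
    list(bin_edges = edges, counts = tbl$count, n_events = sum(tbl$count),
         bin_width = tbl$bin_hi_kDa[1] - tbl$bin_lo_kDa[1]),
    class = "mass_histogram"
  )
}

#' Write / read the results table (TSV)
#'
#' One row per sample: class percentages, capsid and payload masses, event
#' count and background fraction (columns as in [composition_row()]).
#'
#' @param results List of `composition_result`s or a tibble of
#'   [composition_row()]s.
#' @param path File path.
#' @export
write_results_tsv <- function(results, path) {
  tbl <- if (is.data.frame(results)) {
    results
  } else {
    dplyr::bind_rows(lapply(results, composition_row))
  }
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), n_events = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' Write / read a calibration report (JSON)
#'
#' Variant, slope, intercept, R^2 and the per-point residuals.
#'
#' @param model A `calibration_model`.
#' @param path File path.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  pts <- lapply(seq_along(model$points), function(i) {
    p <- model$points[[i]]
    list(name = p$name, reference_mass = p$reference_mass,
         mean_contrast = p$mean_contrast, n_events = p$n_events,
         residual = model$residuals[i])
  })
  jsonlite::write_json(
    list(variant = model$variant, slope = model$slope,
         intercept = model$intercept, r_squared = model$r_squared,
         points = pts),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  points <- lapply(j$points, function(p) {
    structure(list(name = p$name, reference_mass = p$reference_mass,
                   mean_contrast = p$mean_contrast,
                   n_events = as.integer(p$n_events)),
              class = "calibration_point")
  })
  structure(
    list(slope = j$slope, intercept = j$intercept, r_squared = j$r_squared,
         points = points,
         residuals = vapply(j$points, function(p) p$residual, numeric(1)),
         variant = j$variant),
    class = "calibration_model"
  )
}

#' Write / read a sample manifest (YAML)
#'
#' A manifest names the samples of a run: per sample an id, a dilution
#' factor, and either an event-file path or a preset name.
#'
#' @param manifest List of sample entries (each a named list).
#' @param path File path.
#' @export
write_manifest_yaml <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest_yaml
#' @export
read_manifest_yaml <- function(path) {
  yaml::read_yaml(path)
}
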