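#' Run the full analysis pipeline over a set of samples
#'
#' Calibrate, apply, gate, fit, quantify and (optionally) estimate titers
#' for every sample of a run, from in-memory event sets or event CSV files.
#' The stages mirror a measurement sequence: a calibration standard fixes
#' the contrast-to-mass line, mostly-empty/mostly-full references place the
#' subpopulation gates, and each sample is then quantified against them.
#' Per-sample failures are caught, logged and reported; the remaining
#' samples are still processed. Given identical inputs and seeds the output
#' is deterministic.
#'
#' @param config A list with elements:
#' \describe{
#'   \item{calibrant}{[event_set()] (or list of them, merged) of the
#'     calibration standard; or a file path.}
#'   \item{calibrant_mass}{Reference mass of the standard, kDa.}
#'   \item{variant}{Calibration variant, see [fit_calibration()]
#'     (default `"zero_aav9e"`).}
#'   \item{gates}{A [subpop_gates()], or omit and supply `mec`/`mfc`.}
#'   \item{mec, mfc}{Reference [event_set()]s (or file paths) used to place
#'     the gates via [fit_reference_peak()] when `gates` is absent.}
#'   \item{samples}{Named list of [event_set()]s or file paths.}
#'   \item{bin_width}{Histogram bin width, kDa (default 40).}
#'   \item{k}{Gate SD multiplier (default 3).}
#'   \item{min_window_events}{Per-window Gaussian-fit threshold (default 50).}
#'   \item{min_calibrant_events}{Calibrant summary threshold (default 100).}
#'   \item{kappa, known_titer, titer_standard}{Optional: a landing factor,
#'     or a standard event set plus its known titer to calibrate one; when
#'     present every sample also gets a [estimate_titer()] result.}
#' }
#' @return A results bundle: list with `calibration`, `gates`, `results`
#'   (tibble, one row per successfully analysed sample), `compositions`,
#'   `titers`, `replicate_stats` (when >= 2 samples succeeded), `errors`
#'   (named list of failure messages) and `log` (character).
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(
    list(variant = "zero_aav9e", bin_width = 40, k = 3,
         min_window_events = 50L, min_calibrant_events = 100L,
         samples = list()),
    config
  )
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  as_event_set <- function(x, id) {
    if (inherits(x, "event_set")) x else read_event_csv(x, sample_id = id)
  }

  # --- calibration -----------------------------------------------------
  calibrant <- cfg$calibrant
  if (!is.list(calibrant) || inherits(calibrant, "event_set")) {
    calibrant <- list(calibrant)
  }
  calibrant <- lapply(seq_along(calibrant), function(i)
    as_event_set(calibrant[[i]], sprintf("calibrant_%d", i)))
  point <- summarize_calibrant(calibrant, cfg$calibrant_mass,
                               min_events = cfg$min_calibrant_events)
  say("calibrant: %d events, median contrast %.6g (threshold %d)",
      point$n_events, point$mean_contrast, cfg$min_calibrant_events)
  extra <- if (cfg$variant == "tg_aav9e") {
    tg <- summarize_calibrant(as_event_set(cfg$tg, "tg"), cfg$tg_mass,
                              min_events = cfg$min_calibrant_events)
    list(tg)
  } else list()
  calibration <- fit_calibration(c(extra, list(point)), cfg$variant)
  say("calibration %s: slope %.6g, intercept %.6g, R^2 %.6g",
      calibration$variant, calibration$slope, calibration$intercept,
      calibration$r_squared)

  # --- gates -----------------------------------------------------------
  gates <- cfg$gates
  if (is.null(gates)) {
    mec <- apply_calibration(calibration, as_event_set(cfg$mec, "meC"))
    mfc <- apply_calibration(calibration, as_event_set(cfg$mfc, "mfC"))
    mec_peak <- fit_reference_peak(mec, bin_width = cfg$bin_width)
    mfc_peak <- fit_reference_peak(mfc, bin_width = cfg$bin_width)
    gates <- set_gates_from_references(mec_peak, mfc_peak, k = cfg$k)
    say("gates from references: meC %.5g +- %.4g, mfC %.5g +- %.4g, k = %g",
        mec_peak$mean, mec_peak$sd, mfc_peak$mean, mfc_peak$sd, cfg$k)
  }
  say("gates: cutoff %.5g, boundaries %.5g / %.5g / %.5g",
      gates$lower_cutoff, gates$boundaries[1], gates$boundaries[2],
      gates$boundaries[3])

  # --- optional titer calibration --------------------------------------
  kappa <- cfg$kappa
  if (is.null(kappa) && !is.null(cfg$titer_standard)) {
    kappa <- calibrate_kappa(as_event_set(cfg$titer_standard, "standard"),
                             cfg$known_titer)
    say("kappa calibrated: %.6g ev/s per cp/mL", kappa)
  }

  # --- samples ---------------------------------------------------------
  ids <- names(cfg$samples)
  if (is.null(ids)) ids <- sprintf("sample_%d", seq_along(cfg$samples))
  compositions <- list()
  titers <- list()
  errors <- list()
  for (i in seq_along(cfg$samples)) {
    id <- ids[i]
    res <- tryCatch({
      es <- as_event_set(cfg$samples[[i]], id)
      es$sample_id <- id
      es <- apply_calibration(calibration, es)
      comp <- quantify(es, gates, bin_width = cfg$bin_width,
                       min_events = cfg$min_window_events)
      if (!is.null(kappa)) {
        titers[[id]] <<- estimate_titer(es, kappa,
                                        reference_titer = cfg$reference_titer)
      }
      comp
    }, error = function(e) {
      errors[[id]] <<- conditionMessage(e)
      say("sample '%s' failed: %s", id, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      compositions[[id]] <- res
      say("sample '%s': n = %d, %%F = %.2f", id, res$n_events_used,
          res$percentages[["full"]])
    }
  }

  results <- if (length(compositions)) {
    dplyr::bind_rows(lapply(compositions, composition_row))
  } else {
    tibble::tibble()
  }
  rep_stats <- if (length(compositions) >= 2L) {
    replicate_stats(compositions)
  } else NULL

  list(calibration = calibration, gates = gates, results = results,
       compositions = compositions, titers = titers,
       replicate_stats = rep_stats, errors = errors, log = log)
}

#' Compare pipeline percentages against an external reference
#'
#' Joins per-sample subpopulation percentages from this pipeline with
#' externally determined reference percentages (e.g. from analytical
#' ultracentrifugation) and reports class-wise differences
#' (pipeline minus reference) plus the maximum absolute difference.
#'
#' @param results Tibble with columns `sample_id`, `pct_empty`,
#'   `pct_partial`, `pct_full`, `pct_overfull` (e.g. a bundle's `results`),
#'   or a list of `composition_result`s.
#' @param reference Tibble with the same columns holding the reference
#'   percentages.
#' @return Object of class `comparison_report`: tibble `differences`
#'   (per sample and class) and `max_abs_difference`.
#' @export
#' @examples
#' mp <- tibble::tibble(sample_id = "mix_a", pct_empty = 60, pct_partial = 25,
#'                      pct_full = 11.2, pct_overfull = 3.8)
#' auc <- tibble::tibble(sample_id = "mix_a", pct_empty = 75, pct_partial = 20,
#'                       pct_full = 1.6, pct_overfull = 3.4)
#' compare_composition(mp, auc)
compare_composition <- function(results, reference) {
  if (!is.data.frame(results)) {
    results <- dplyr::bind_rows(lapply(results, composition_row))
  }
  reference <- tibble::as_tibble(reference)
  cls_cols <- paste0("pct_", aav_classes)
  missing_ids <- setdiff(results$sample_id, reference$sample_id)
  extra_ids <- setdiff(reference$sample_id, results$sample_id)
  if (length(missing_ids) || length(extra_ids)) {
    stop("sample ids do not match; unmatched: ",
         paste(c(missing_ids, extra_ids), collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(
    results[, c("sample_id", cls_cols)],
    reference[, c("sample_id", cls_cols)],
    by = "sample_id", suffix = c("_mp", "_ref")
  )
  diffs <- dplyr::bind_rows(lapply(aav_classes, function(cl) {
    tibble::tibble(
      sample_id = joined$sample_id,
      class_label = cl,
      mp = joined[[paste0("pct_", cl, "_mp")]],
      reference = joined[[paste0("pct_", cl, "_ref")]],
      difference = joined[[paste0("pct_", cl, "_mp")]] -
        joined[[paste0("pct_", cl, "_ref")]]
    )
  }))
  structure(
    list(differences = diffs,
         max_abs_difference = max(abs(diffs$difference))),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> max |difference| =",
      format(x$max_abs_difference, digits = 4), "points\n")
  print(x$differences)
  invisible(x)
}
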