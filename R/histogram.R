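#' Build a mass histogram from calibrated events
#'
#' Bins the calibrated masses of the binding events into uniform bins of
#' `bin_width` kDa (default 40, the analysis convention used throughout),
#' starting at `lower_cutoff` and extending to cover the largest mass. Bins
#' are half-open `[lo, hi)`: an event exactly on an interior edge falls in
#' the upper bin. Events below the cutoff are excluded.
#'
#' @param es A mass-annotated [event_set()] (see [apply_calibration()]).
#' @param bin_width Bin width in kDa (> 0).
#' @param lower_cutoff Lowest mass retained, in kDa.
#' @return An object of class `mass_histogram`: list with `bin_edges`
#'   (length `nbins + 1`), `counts`, `n_events`, `bin_width`.
#' @export
build_histogram <- function(es, bin_width = 40, lower_cutoff = 0) {
  stopifnot(inherits(es, "event_set"))
  if (!("mass_kDa" %in% names(es$events))) {
    stop("event set is not mass-annotated; run apply_calibration() first",
         call. = FALSE)
  }
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  mass <- binding_events(es)$mass_kDa
  mass <- mass[mass >= lower_cutoff]
  if (length(mass) == 0L) {
    stop("no binding events at or above the lower cutoff (",
         lower_cutoff, " kDa)", call. = FALSE)
  }
  nbins <- max(1L, ceiling((max(mass) - lower_cutoff) / bin_width))
  # an event exactly on the top edge belongs to the (open) upper side:
  # add one bin so findInterval never right-closes
  if (max(mass) >= lower_cutoff + nbins * bin_width) nbins <- nbins + 1L
  edges <- lower_cutoff + bin_width * (0:nbins)
  idx <- findInterval(mass, edges)  # [lo, hi) semantics
  counts <- tabulate(idx, nbins)
  structure(
    list(bin_edges = edges, counts = counts, n_events = length(mass),
         bin_width = bin_width),
    class = "mass_histogram"
  )
}

#' Bin centers of a mass histogram
#' @param hist A `mass_histogram`.
#' @return Numeric vector of bin midpoints in kDa.
#' @export
bin_centers <- function(hist) {
  stopifnot(inherits(hist, "mass_histogram"))
  (utils::head(hist$bin_edges, -1) + utils::tail(hist$bin_edges, -1)) / 2
}

#' @export
print.mass_histogram <- function(x, ...) {
  cat(sprintf("<mass_histogram> %d events in %d bins of %g kDa over [%g, %g)\n",
              x$n_events, length(x$counts), x$bin_width,
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}
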