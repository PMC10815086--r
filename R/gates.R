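#' Subpopulation mass gates
#'
#' Three ascending mass boundaries `b1 < b2 < b3` split the mass axis into
#' the empty (E), partially filled (PF), full (F) and overfull (OF) windows;
#' `lower_cutoff` excludes sub-capsid background below the empty window.
#'
#' @param boundaries Numeric length 3, strictly ascending, kDa.
#' @param lower_cutoff Mass below which events are treated as background.
#' @param k The SD multiplier the gates were built with, recorded for
#'   provenance (may be `NA` for manually specified gates).
#' @return An object of class `subpop_gates`.
#' @export
subpop_gates <- function(boundaries, lower_cutoff, k = NA_real_) {
  if (length(boundaries) != 3L || any(diff(boundaries) <= 0)) {
    stop("`boundaries` must be three strictly ascending masses", call. = FALSE)
  }
  if (lower_cutoff >= boundaries[1]) {
    stop("`lower_cutoff` must lie below the first boundary", call. = FALSE)
  }
  structure(list(boundaries = boundaries, lower_cutoff = lower_cutoff, k = k),
            class = "subpop_gates")
}

#' @export
print.subpop_gates <- function(x, ...) {
  cat(sprintf("<subpop_gates> cutoff %.4g | E | %.4g | PF | %.4g | F | %.4g | OF (k = %s)\n",
              x$lower_cutoff, x$boundaries[1], x$boundaries[2],
              x$boundaries[3], format(x$k)))
  invisible(x)
}

#' Set subpopulation gates from reference-sample peak fits
#'
#' Places the E/PF/F/OF mass boundaries from single-Gaussian fits of a
#' mostly-empty capsid reference (meC) and a mostly-full capsid reference
#' (mfC), the strategy used when analysing a serotype for which gates are
#' not yet established:
#' `b1 = mu_e + k*sigma_e`, `b2 = mu_f - k*sigma_f`, `b3 = mu_f + k*sigma_f`
#' and `lower_cutoff = mu_e - k*sigma_e`. If the references overlap so that
#' `b2 <= b1`, `b2` falls back to the midpoint of the two peak means.
#'
#' @param mec,mfc [gaussian_component()]-like objects (fields `mean`, `sd`)
#'   for the mostly-empty and mostly-full reference peaks; see
#'   [fit_reference_peak()].
#' @param k SD multiplier (default 3).
#' @return A [subpop_gates()].
#' @export
#' @examples
#' e <- gaussian_component(3740, 60, 1, "empty")
#' f <- gaussian_component(5000, 60, 1, "full")
#' set_gates_from_references(e, f)  # boundaries 3920, 4820, 5180
set_gates_from_references <- function(mec, mfc, k = 3) {
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (!(mec$mean < mfc$mean)) {
    stop("mostly-empty reference mean (", mec$mean,
         ") must lie below mostly-full reference mean (", mfc$mean, ")",
         call. = FALSE)
  }
  b1 <- mec$mean + k * mec$sd
  b2 <- mfc$mean - k * mfc$sd
  b3 <- mfc$mean + k * mfc$sd
  if (b2 <= b1) {
    # references too wide to resolve a partial window: fall back to the
    # midpoint, pulling b1 in with it if the empty window still overlaps
    b2 <- (mec$mean + mfc$mean) / 2
    if (b1 >= b2) b1 <- (mec$mean + b2) / 2
  }
  subpop_gates(c(b1, b2, b3), lower_cutoff = mec$mean - k * mec$sd, k = k)
}

#' Classify calibrated masses into subpopulation windows
#'
#' Vectorized gate classifier: masses below the cutoff are `"background"`,
#' then `[cutoff, b1)` is empty, `[b1, b2)` partial, `[b2, b3)` full and
#' `[b3, Inf)` overfull (half-open windows, matching the histogram
#' convention).
#'
#' @param mass Numeric vector of masses in kDa.
#' @param gates A [subpop_gates()].
#' @return Factor with levels background, empty, partial, full, overfull.
#' @export
classify_mass <- function(mass, gates) {
  stopifnot(inherits(gates, "subpop_gates"))
  cuts <- c(-Inf, gates$lower_cutoff, gates$boundaries, Inf)
  lev <- c("background", aav_classes)
  idx <- findInterval(mass, cuts)  # 1..5, [lo, hi)
  factor(lev[idx], levels = lev)
}

#' Fit a single Gaussian to the dominant peak of a reference sample
#'
#' Builds a mass histogram of the (calibrated) reference events and fits one
#' Gaussian to the bins within `window_halfwidth` of the modal bin — enough
#' to locate and scale a reference peak even when a minor second population
#' is present (a mostly-empty reference still carries some full capsids, and
#' vice versa).
#'
#' @param es Mass-annotated [event_set()] of the reference sample.
#' @param bin_width Histogram bin width in kDa.
#' @param lower_cutoff Passed to [build_histogram()]; defaults to 2000 kDa,
#'   below any intact capsid, so crude-extract background does not pull the
#'   mode.
#' @param window_halfwidth Half-width of the fit window around the modal bin
#'   center, kDa (default 400).
#' @return A [gaussian_component()] with `class_label = "reference"`.
#' @export
fit_reference_peak <- function(es, bin_width = 40, lower_cutoff = 2000,
                               window_halfwidth = 400) {
  hist <- build_histogram(es, bin_width = bin_width,
                          lower_cutoff = lower_cutoff)
  centers <- bin_centers(hist)
  mode_center <- centers[which.max(hist$counts)]
  keep <- abs(centers - mode_center) <= window_halfwidth
  fit <- fit_gaussian_bins(centers[keep], hist$counts[keep],
                           label = "reference")
  fit
}
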