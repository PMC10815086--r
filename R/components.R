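#' Gaussian component of a mass histogram
#'
#' One fitted subpopulation peak: amplitude is the peak height in events per
#' bin, so the implied event count under the peak is
#' `amplitude * sd * sqrt(2*pi) / bin_width`.
#'
#' @param mean,sd Peak location and width in kDa (`sd > 0`).
#' @param amplitude Peak height in events per bin (>= 0).
#' @param class_label One of empty, partial, full, overfull, background,
#'   or reference.
#' @return Object of class `gaussian_component`.
#' @export
gaussian_component <- function(mean, sd, amplitude = 1,
                               class_label = "reference") {
  if (sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  structure(list(mean = mean, sd = sd, amplitude = amplitude,
                 class_label = class_label),
            class = "gaussian_component")
}

#' @export
print.gaussian_component <- function(x, ...) {
  cat(sprintf("<gaussian_component %s> mean %.5g kDa, sd %.4g kDa, amplitude %.4g\n",
              x$class_label, x$mean, x$sd, x$amplitude))
  invisible(x)
}

# Nonlinear least-squares fit of A * exp(-(x - mu)^2 / (2 s^2)) to bin
# counts, initialised at the count-weighted centroid. Degenerate windows
# (all counts in one bin) return a component with sd = bin spacing / 2.
fit_gaussian_bins <- function(centers, counts, label = "reference") {
  keep <- counts > 0
  if (sum(keep) == 0L) stop("no counts to fit", call. = FALSE)
  w <- counts[keep]
  x <- centers[keep]
  mu0 <- sum(w * x) / sum(w)
  s0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  spacing <- if (length(centers) > 1) min(diff(sort(centers))) else 1
  if (!is.finite(s0) || s0 <= 0) s0 <- spacing / 2
  a0 <- max(counts)
  if (sum(keep) < 3L) {
    return(gaussian_component(mu0, s0, a0, label))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ A * exp(-(centers - mu)^2 / (2 * s^2)),
      start = list(A = a0, mu = mu0, s = s0),
      lower = c(A = 0, mu = min(centers), s = spacing / 10),
      upper = c(A = Inf, mu = max(centers), s = diff(range(centers)) + spacing),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("Gaussian fit failed in window '", label, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  gaussian_component(unname(cf["mu"]), unname(cf["s"]), unname(cf["A"]), label)
}

#' Fit Gaussian components within the gate windows
#'
#' For each subpopulation window (empty, partial, full, overfull) holding at
#' least `min_events` histogram counts, fits a single Gaussian to the bin
#' counts of that window by nonlinear least squares. Windows below the
#' threshold yield no component (not an error): the partially-filled and
#' overfull classes frequently lack a resolvable peak.
#'
#' @param hist A [build_histogram()] result.
#' @param gates A [subpop_gates()].
#' @param min_events Minimum events in a window for a fit (default 50).
#' @return Named list of [gaussian_component()]s (subset of the four
#'   classes).
#' @export
fit_components <- function(hist, gates, min_events = 50L) {
  stopifnot(inherits(hist, "mass_histogram"), inherits(gates, "subpop_gates"))
  centers <- bin_centers(hist)
  windows <- data.frame(
    class = aav_classes,
    lo = c(gates$lower_cutoff, gates$boundaries),
    hi = c(gates$boundaries, Inf)
  )
  out <- list()
  for (i in seq_len(nrow(windows))) {
    keep <- centers >= windows$lo[i] & centers < windows$hi[i]
    if (sum(hist$counts[keep]) < min_events) next
    out[[windows$class[i]]] <-
      fit_gaussian_bins(centers[keep], hist$counts[keep],
                        label = windows$class[i])
  }
  if (length(out) == 0L) {
    stop("no gate window holds at least ", min_events, " events", call. = FALSE)
  }
  out
}

#' Whole-axis Gaussian mixture fit by expectation-maximization
#'
#' Alternative to the windowed fits: an unconstrained variable-variance
#' Gaussian mixture over the raw calibrated masses, fitted by EM
#' (via \pkg{mclust}). On well-separated data its component means agree with
#' the windowed nonlinear-least-squares fits to within a bin width; unlike
#' them it needs the number of components up front and no gates.
#'
#' @param mass Numeric vector of calibrated masses (kDa).
#' @param G Number of mixture components.
#' @return Tibble with one row per component, sorted by mean: columns
#'   `mean`, `sd`, `proportion`.
#' @export
fit_mixture_em <- function(mass, G) {
  stopifnot(length(mass) > G)
  fit <- mclust::Mclust(mass, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("EM mixture fit did not converge", call. = FALSE)
  ord <- order(fit$parameters$mean)
  tibble::tibble(
    mean = unname(fit$parameters$mean[ord]),
    sd = sqrt(unname(fit$parameters$variance$sigmasq[ord])),
    proportion = unname(fit$parameters$pro[ord])
  )
}
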