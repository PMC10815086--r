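# calibrated event set straight from masses (identity-ish line)
es_from_mass <- function(mass, duration = 60) {
  ev <- tibble::tibble(
    time_s = seq_along(mass) * duration / (length(mass) + 1),
    contrast = mass / 2e4,
    event_type = "binding",
    mass_kDa = mass
  )
  event_set(ev, acquisition = acquisition_config())
}

test_that("histogram bins are uniform, half-open and conserve events", {
  es <- es_from_mass(rep(3700, 10))
  h <- build_histogram(es, bin_width = 40)
  expect_equal(sum(h$counts), 10L)
  expect_equal(sum(h$counts > 0), 1L)
  expect_true(all(abs(diff(diff(h$bin_edges))) < 1e-9))

  # an event exactly on an interior edge goes to the upper bin
  es2 <- es_from_mass(c(35, 40, 45))
  h2 <- build_histogram(es2, bin_width = 40)
  expect_equal(h2$counts[1:2], c(1L, 2L))

  # conservation above the cutoff on a realistic sample
  es3 <- apply_calibration(fix_cal,
                           sim_preset("reference_aav9", seed = 41,
                                      n_events = 5000))
  h3 <- build_histogram(es3, bin_width = 40,
                        lower_cutoff = fix_gates$lower_cutoff)
  n_above <- sum(binding_events(es3)$mass_kDa >= fix_gates$lower_cutoff)
  expect_equal(h3$n_events, n_above)
  expect_equal(sum(h3$counts), n_above)

  expect_error(build_histogram(es, bin_width = 40, lower_cutoff = 1e6),
               "no binding events")
})

test_that("gates derive from reference peaks by the k-sigma rule", {
  e <- gaussian_component(3740, 60, 1, "empty")
  f <- gaussian_component(5000, 60, 1, "full")
  g <- set_gates_from_references(e, f, k = 3)
  expect_equal(g$boundaries, c(3920, 4820, 5180))
  expect_equal(g$lower_cutoff, 3560)

  # vanishing widths collapse the boundaries onto the peak means
  g0 <- set_gates_from_references(gaussian_component(3740, 1e-9),
                                  gaussian_component(5000, 1e-9), k = 3)
  expect_equal(g0$boundaries[1], 3740, tolerance = 1e-6)
  expect_equal(g0$boundaries[2], 5000, tolerance = 1e-6)
  expect_equal(g0$boundaries[3], 5000, tolerance = 1e-6)

  # overlapping references fall back to the midpoint rule
  go <- set_gates_from_references(gaussian_component(3740, 300),
                                  gaussian_component(5000, 300), k = 3)
  expect_equal(go$boundaries[2], (3740 + 5000) / 2)

  expect_error(set_gates_from_references(f, e), "below")
  expect_error(set_gates_from_references(e, f, k = 0), "k")
})

test_that("windowed Gaussian fit recovers generating peak parameters", {
  set.seed(61)
  mass <- rnorm(2000, 3740, 60)
  h <- build_histogram(es_from_mass(mass), bin_width = 40,
                       lower_cutoff = 3000)
  fit <- fit_gaussian_bins(bin_centers(h), h$counts, "empty")
  expect_lt(abs(fit$mean - 3740), 3 * 60 / sqrt(2000))
  expect_lt(abs(fit$sd - 60) / 60, 0.15)
})

test_that("windowed and EM mixture fits agree on well-separated peaks", {
  set.seed(62)
  mass <- c(rnorm(1500, 3740, 60), rnorm(1500, 5000, 60))
  es <- es_from_mass(mass)
  gates <- subpop_gates(c(4100, 4700, 5400), lower_cutoff = 3300, k = 3)
  h <- build_histogram(es, bin_width = 40, lower_cutoff = 3300)
  comp <- fit_components(h, gates)
  em <- fit_mixture_em(mass, G = 2)
  expect_lt(abs(comp$empty$mean - em$mean[1]), 40)  # one bin width
  expect_lt(abs(comp$full$mean - em$mean[2]), 40)
  # windows without events yield no component and no error
  expect_false("overfull" %in% names(comp))
  expect_false("partial" %in% names(comp))
})

test_that("empty-window threshold suppresses fits without erroring", {
  set.seed(63)
  mass <- rnorm(500, 3740, 60)
  h <- build_histogram(es_from_mass(mass), bin_width = 40,
                       lower_cutoff = 3300)
  gates <- subpop_gates(c(4100, 4700, 5400), lower_cutoff = 3300, k = 3)
  comp <- fit_components(h, gates, min_events = 50)
  expect_named(comp, "empty")
  expect_error(fit_components(h, gates, min_events = 1e6), "at least")
})

test_that("gate classification matches a brute-force per-event classifier", {
  es <- apply_calibration(fix_cal,
                          sim_preset("harvest_mix_a", seed = 43,
                                     n_events = 3000))
  mass <- binding_events(es)$mass_kDa
  fast <- classify_mass(mass, fix_gates)
  b <- fix_gates$boundaries
  slow <- vapply(mass, function(m) {
    if (m < fix_gates$lower_cutoff) "background"
    else if (m < b[1]) "empty"
    else if (m < b[2]) "partial"
    else if (m < b[3]) "full"
    else "overfull"
  }, character(1))
  expect_identical(as.character(fast), slow)
})

test_that("quantification partitions events and normalizes percentages", {
  es <- apply_calibration(fix_cal,
                          sim_preset("reference_aav9", seed = 44,
                                     n_events = 5000))
  q <- quantify(es, fix_gates)
  expect_equal(sum(q$percentages), 100, tolerance = 1e-6)
  cls <- classify_mass(binding_events(es)$mass_kDa, fix_gates)
  expect_equal(q$n_events_used, sum(cls != "background"))
  counts <- table(cls)[c("empty", "partial", "full", "overfull")]
  expect_equal(unname(100 * as.numeric(counts) / q$n_events_used),
               unname(q$percentages))
  # payload is the difference of the fitted peak means
  expect_equal(q$payload_mass, q$full_mass - q$empty_mass)
})

test_that("reference-sample percentages recover the generating composition", {
  es <- apply_calibration(fix_cal,
                          sim_preset("reference_aav9", seed = 45,
                                     n_events = 5000))
  q <- quantify(es, fix_gates)
  for (i in 1:4) {
    cls <- c("empty", "partial", "full", "overfull")[i]
    expect_lt(abs(q$percentages[[cls]] - 100 * ref_props[i]),
              multinom_se3(ref_props[i], 5000))
  }
})

test_that("degenerate samples quantify sensibly", {
  # all events in one window: that class 100%, the rest 0
  es <- es_from_mass(rnorm(500, 3740, 10))
  gates <- subpop_gates(c(4100, 4700, 5400), lower_cutoff = 3300, k = 3)
  q <- quantify(es, gates)
  expect_equal(unname(q$percentages),
               c(100, 0, 0, 0))
  # full component missing: payload absent (NA), not zero
  expect_true(is.na(q$full_mass))
  expect_true(is.na(q$payload_mass))
})

test_that("raising the full-window lower boundary never increases %full", {
  es <- apply_calibration(fix_cal,
                          sim_preset("reference_aav9", seed = 46,
                                     n_events = 4000))
  b <- fix_gates$boundaries
  pct_full <- vapply(seq(b[1] + 1, b[3] - 1, length.out = 8), function(b2) {
    g <- subpop_gates(c(b[1], b2, b[3]), fix_gates$lower_cutoff)
    quantify(es, g, components = list())$percentages[["full"]]
  }, numeric(1))
  expect_true(all(diff(pct_full) <= 0))
})

test_that("area-based percentages agree with event counting when peaks resolve", {
  # four well-separated Gaussian classes, no uniform partial fill
  mix <- mixture_spec(tibble::tibble(
    class_label = c("empty", "partial", "full", "overfull"),
    mass_kDa = c(3740, 4400, 5000, 5600),
    sd_kDa = 60,
    proportion = c(0.4, 0.2, 0.3, 0.1)
  ))
  acq <- acquisition_config(seed = 47)
  es <- apply_calibration(fix_cal, simulate_sample(mix, acq, n_events = 6000))
  gates <- subpop_gates(c(4070, 4700, 5300), lower_cutoff = 3410, k = 3)
  qc <- quantify(es, gates, percentages_from = "counts")
  qa <- quantify(es, gates, percentages_from = "areas")
  expect_lt(max(abs(qc$percentages - qa$percentages)), 2)
})

test_that("composition recovery holds over many seeded simulations", {
  classes <- c("empty", "partial", "full", "overfull")
  err <- matrix(NA_real_, 100, 4, dimnames = list(NULL, classes))
  mean_err <- matrix(NA_real_, 100, 2)
  truth <- preset("reference_aav9")$mixture
  for (s in 1:100) {
    es <- apply_calibration(fix_cal,
                            sim_preset("reference_aav9", seed = 7000L + s,
                                       n_events = 5000))
    q <- quantify(es, fix_gates)
    err[s, ] <- q$percentages[classes] - 100 * ref_props
    mean_err[s, ] <- c(q$empty_mass - 3740,
                       q$full_mass - truth$components$mass_kDa[3])
  }
  expect_true(all(colMeans(abs(err)) <= 1.5))
  expect_lt(abs(mean(mean_err[, 1])), 40)  # one bin width
  expect_lt(abs(mean(mean_err[, 2])), 40)
})

test_that("replicate statistics follow the n-1 SD and RSD definitions", {
  make_res <- function(pcts, id = "s") {
    structure(list(sample_id = id,
                   percentages = stats::setNames(pcts,
                     c("empty", "partial", "full", "overfull")),
                   components = list(), empty_mass = 3740, full_mass = 5000,
                   partial_mass = 4300, overfull_mass = 5400,
                   payload_mass = 1260, n_events_used = 1000L,
                   background_fraction = 0, gates = fix_gates),
              class = "composition_result")
  }
  # hand-checked: 50 and 54 -> mean 52, sd 2.828, rsd 5.44%
  rs <- replicate_stats(list(make_res(c(50, 20, 20, 10)),
                             make_res(c(54, 16, 20, 10))))
  row <- rs$stats[rs$stats$quantity == "pct_empty", ]
  expect_equal(row$mean, 52)
  expect_equal(row$sd, sqrt(8), tolerance = 1e-6)
  expect_equal(row$rsd, 100 * sqrt(8) / 52, tolerance = 1e-4)

  same <- replicate_stats(list(make_res(c(50, 20, 20, 10)),
                               make_res(c(50, 20, 20, 10))))
  expect_true(all(same$stats$sd == 0))
  expect_true(all(same$stats$rsd[same$stats$mean != 0] == 0))

  expect_error(replicate_stats(list(make_res(c(50, 20, 20, 10)))),
               "at least 2")
})
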