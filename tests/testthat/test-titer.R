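set_from_n <- function(n, duration = 60, dilution = 1, n_unbind = 0) {
  ev <- tibble::tibble(
    time_s = seq_len(n + n_unbind) * duration / (n + n_unbind + 1),
    contrast = 0.187,
    event_type = rep(c("binding", "unbinding"), c(n, n_unbind))
  )
  event_set(ev, dilution_factor = dilution,
            acquisition = acquisition_config(duration = duration))
}

test_that("binding count rate is bindings over duration", {
  expect_equal(count_rate(set_from_n(6000)), 100)
  expect_equal(count_rate(set_from_n(0)), 0)
  # unbinding events do not enter the rate
  expect_equal(count_rate(set_from_n(6000, n_unbind = 600)), 100)
})

test_that("kappa calibration follows its definition and scale invariance", {
  expect_equal(calibrate_kappa(set_from_n(6000), known_titer = 1e11), 1e-9)
  # doubling both rate and titer leaves kappa unchanged
  expect_equal(calibrate_kappa(set_from_n(12000), known_titer = 2e11), 1e-9)
  # measurement dilution scales the concentration in the well
  expect_equal(calibrate_kappa(set_from_n(3000, dilution = 2),
                               known_titer = 1e11), 1e-9)
  expect_error(calibrate_kappa(set_from_n(0), known_titer = 1e11),
               "zero binding count rate")
  expect_error(calibrate_kappa(set_from_n(100), known_titer = 0), "> 0")
})

test_that("kappa recovers the generating landing factor over many seeds", {
  kappas <- vapply(1:100, function(s) {
    std <- sim_preset("calibrant_aav9e", seed = 8000L + s)
    calibrate_kappa(std, known_titer = 3.3e11)
  }, numeric(1))
  se <- sd(kappas) / sqrt(length(kappas))
  expect_lt(abs(mean(kappas) - 1e-9), 3 * se)
})

test_that("titer estimate inverts the landing model with a Poisson interval", {
  est <- estimate_titer(set_from_n(6000), kappa = 1e-9)
  expect_equal(est$titer, 1e11)
  expect_lt(est$ci_lower, est$titer)
  expect_gt(est$ci_upper, est$titer)
  # interval has roughly sqrt(n) relative width
  expect_equal(est$ci_upper / est$titer, 1 + 1.96 / sqrt(6000),
               tolerance = 0.01)

  # dilution scales the estimate back to the undiluted sample
  expect_equal(estimate_titer(set_from_n(3000, dilution = 2), 1e-9)$titer,
               1e11)

  est0 <- estimate_titer(set_from_n(0), kappa = 1e-9)
  expect_equal(est0$titer, 0)
  expect_equal(est0$ci_lower, 0)
  expect_gt(est0$ci_upper, 0)

  ref <- estimate_titer(set_from_n(6600), kappa = 1e-9,
                        reference_titer = 1e11)
  expect_equal(ref$relative_error, 10)
})

test_that("five-replicate mean titer recovers the generating concentration", {
  std <- sim_preset("calibrant_aav9e", seed = 301)
  kappa <- calibrate_kappa(std, known_titer = 3.3e11)
  p <- preset("reference_aav9", seed = 400)
  reps <- simulate_replicates(p$mixture, p$acquisition, n_replicates = 5)
  titers <- vapply(reps, function(r) estimate_titer(r, kappa)$titer,
                   numeric(1))
  # combined SE: Poisson noise in the five samples plus kappa's own error
  se_sample <- mean(titers) / sqrt(5 * 6000)
  se_kappa <- mean(titers) / sqrt(3.3e11 * 1e-9 * 60)
  expect_lt(abs(mean(titers) - 1e11),
            3 * sqrt(se_sample^2 + se_kappa^2))
})

test_that("estimated titer scales linearly with concentration", {
  std <- sim_preset("calibrant_aav9e", seed = 302)
  kappa <- calibrate_kappa(std, known_titer = 3.3e11)
  concs <- c(4.3e11, 2e11, 1.5e11, 1e11)
  means <- vapply(seq_along(concs), function(i) {
    titers <- vapply(1:50, function(s) {
      p <- preset("reference_aav9", seed = 9000L + 100L * i + s)
      p$acquisition$concentration <- concs[i]
      estimate_titer(simulate_sample(p$mixture, p$acquisition), kappa)$titer
    }, numeric(1))
    mean(titers)
  }, numeric(1))
  expect_gt(summary(lm(means ~ concs))$r.squared, 0.99)
  # recovery at every concentration within a few percent
  expect_true(all(abs(means / concs - 1) < 0.05))
})

test_that("replicate titer SD grows with the mean count as Poisson predicts", {
  counts_at <- function(conc, seeds) {
    vapply(seeds, function(s) {
      p <- preset("reference_aav9", seed = s)
      p$acquisition$concentration <- conc
      nrow(binding_events(simulate_sample(p$mixture, p$acquisition)))
    }, numeric(1))
  }
  lo <- counts_at(1e11, 10001:10060)
  hi <- counts_at(4e11, 10101:10160)
  # absolute spread grows roughly as sqrt(mean): ratio near 2, far from 4
  ratio <- sd(hi) / sd(lo)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.4)
})

test_that("an unmixed buffer-dilution sample overestimates the titer", {
  std <- sim_preset("calibrant_aav9e", seed = 303)  # buffer-free standard
  kappa <- calibrate_kappa(std, known_titer = 3.3e11)
  p <- preset("reference_aav9")
  titers <- vapply(1:20, function(s) {
    acq <- acquisition_config(mode = "buffer_dilution_auto_unmixed",
                              seed = 11000L + s)
    estimate_titer(simulate_sample(p$mixture, acq), kappa)$titer
  }, numeric(1))
  expect_gt(mean(titers), 1e11)  # truth is 1e11; expectation is 1.6e11
})
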