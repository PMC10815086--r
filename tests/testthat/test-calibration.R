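make_point <- function(mass, contrast, name = "pt", n = 500L) {
  structure(list(name = name, reference_mass = mass, mean_contrast = contrast,
                 n_events = n), class = "calibration_point")
}

test_that("calibrant summary is the median contrast and merges movies", {
  ev <- tibble::tibble(time_s = seq_len(200) / 10, contrast = 0.187,
                       event_type = "binding")
  es <- event_set(ev, sample_id = "AAV9e")
  pt <- summarize_calibrant(es, 3740)
  expect_equal(pt$mean_contrast, 0.187)  # degenerate distribution
  expect_equal(pt$reference_mass, 3740)
  expect_equal(pt$n_events, 200L)

  # merging two movies equals summarizing the concatenated events
  es2 <- sim_preset("calibrant_aav9e", seed = 31)
  es3 <- sim_preset("calibrant_aav9e", seed = 32)
  merged <- summarize_calibrant(list(es2, es3), 3740)
  concat <- event_set(dplyr::bind_rows(es2$events, es3$events))
  expect_equal(merged$mean_contrast,
               summarize_calibrant(concat, 3740)$mean_contrast)
  expect_equal(merged$n_events,
               nrow(binding_events(es2)) + nrow(binding_events(es3)))
})

test_that("too few calibrant events is an explicit error naming the threshold", {
  ev <- tibble::tibble(time_s = 1:10, contrast = 0.1, event_type = "binding")
  expect_error(summarize_calibrant(event_set(ev), 670), "at least 100")
  expect_silent(summarize_calibrant(event_set(ev), 670, min_events = 5))
})

test_that("two-point models interpolate the calibrant masses exactly", {
  c_tg <- 0.0335
  c_9e <- 0.187
  m <- fit_calibration(list(make_point(670, c_tg, "TG"),
                            make_point(3740, c_9e, "AAV9e")), "tg_aav9e")
  expect_lt(abs(predict_mass(m, c_tg) - 670) / 670, 1e-9)
  expect_lt(abs(predict_mass(m, c_9e) - 3740) / 3740, 1e-9)
  expect_equal(m$r_squared, 1)
  expect_true(all(abs(m$residuals) < 1e-9))

  z <- fit_calibration(list(make_point(3740, c_9e, "AAV9e")), "zero_aav9e")
  expect_equal(z$intercept, 0, tolerance = 1e-9)
  expect_equal(predict_mass(z, 0), z$intercept)
  expect_equal(predict_mass(z, c_9e), 3740)
  # linearity through the origin
  expect_equal(predict_mass(z, c_9e / 2), 1870)
})

test_that("three-point fit with a non-collinear middle point has R^2 < 1", {
  # TG contrast pulled off the zero-AAV9e chord
  m <- fit_calibration(list(make_point(670, 0.040, "TG"),
                            make_point(3740, 0.187, "AAV9e")),
                       "zero_tg_aav9e")
  expect_lt(m$r_squared, 1)
  expect_gt(m$r_squared, 0)
  expect_equal(length(m$points), 3L)  # zero point added as an ordinary datum
})

test_that("point order does not change the fitted model", {
  pts <- list(make_point(670, 0.040, "TG"), make_point(3740, 0.187, "AAV9e"))
  m1 <- fit_calibration(pts, "zero_tg_aav9e")
  m2 <- fit_calibration(rev(pts), "zero_tg_aav9e")
  expect_equal(m1$slope, m2$slope)
  expect_equal(m1$intercept, m2$intercept)
  expect_equal(m1$r_squared, m2$r_squared)
})

test_that("least squares matches a brute-force normal-equations solve", {
  pts <- list(make_point(0, 0, "zero"), make_point(670, 0.040, "TG"),
              make_point(3740, 0.187, "AAV9e"))
  m <- fit_calibration(pts, "zero_tg_aav9e")
  x <- vapply(pts, `[[`, numeric(1), "mean_contrast")
  y <- vapply(pts, `[[`, numeric(1), "reference_mass")
  X <- cbind(1, x)
  beta <- unname(solve(t(X) %*% X, t(X) %*% y))
  expect_equal(m$intercept, beta[1, 1])
  expect_equal(m$slope, beta[2, 1])
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_calibration(list(make_point(670, 0.1),
                                    make_point(3740, 0.1)), "tg_aav9e"),
               "singular")
  expect_error(fit_calibration(list(make_point(3740, 0.187)), "tg_aav9e"),
               "expects 2")
  # slope must be positive: heavier calibrant at lower contrast
  expect_error(fit_calibration(list(make_point(670, 0.187),
                                    make_point(3740, 0.0335)), "tg_aav9e"),
               "slope")
})

test_that("calibration annotates binding events and passes unbinding through", {
  es <- sim_preset("reference_aav9", seed = 21, n_events = 1000)
  m <- fit_calibration(list(make_point(3740, 0.187)), "zero_aav9e")
  cal <- apply_calibration(m, es)
  b <- cal$events$event_type == "binding"
  expect_equal(cal$events$mass_kDa[b],
               m$slope * cal$events$contrast[b])
  expect_true(all(is.na(cal$events$mass_kDa[!b])))
  # monotone: higher contrast, higher mass
  ord <- order(cal$events$contrast[b])
  expect_true(!is.unsorted(cal$events$mass_kDa[b][ord]))
})

test_that("fitted calibration recovers the generating line over many seeds", {
  slopes <- vapply(1:100, function(s) {
    es <- sim_preset("calibrant_aav9e", seed = 5000L + s)
    fit_calibration(list(summarize_calibrant(es, 3740)),
                    "zero_aav9e")$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 2e4), 3 * se + 1e-7 * 2e4)
})
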