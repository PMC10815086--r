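# Shared simulation fixtures: a fitted zero+AAV9e calibration and gates
# placed from simulated meC/mfC references, built once per test run.

sim_preset <- function(name, seed, n_events = NULL, ...) {
  p <- preset(name, seed = seed)
  p$acquisition <- utils::modifyList(p$acquisition, list(...))
  class(p$acquisition) <- "acquisition_config"
  simulate_sample(p$mixture, p$acquisition, sample_id = name,
                  n_events = n_events)
}

make_calibration <- function(seed = 101) {
  ces <- sim_preset("calibrant_aav9e", seed)
  pt <- summarize_calibrant(ces, 3740)
  fit_calibration(list(pt), "zero_aav9e")
}

make_gates <- function(model, seed = 201, k = 3) {
  mec <- apply_calibration(model, sim_preset("mec_reference", seed))
  mfc <- apply_calibration(model, sim_preset("mfc_reference", seed + 1))
  set_gates_from_references(fit_reference_peak(mec),
                            fit_reference_peak(mfc), k = k)
}

# fixtures reused across files (fixed seeds, independent of test order)
fix_cal <- make_calibration()
fix_gates <- make_gates(fix_cal)

# true class proportions of the reference preset (printed values sum to 99)
ref_props <- c(33, 6, 52, 8) / 99

# 3x multinomial standard error, in percentage points
multinom_se3 <- function(p, n) 3 * 100 * sqrt(p * (1 - p) / n)
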