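#!/usr/bin/env Rscript
# Generate the simulated measurement campaign used by the downstream
# analysis scripts: calibration standards, gate-setting references, five
# replicates of the purified AAV9 reference sample, and the two harvest
# extracts. One event CSV per movie plus a YAML manifest, under
# scratch/data/.

library(aavmp)

seed <- 20260922L
dir <- "scratch/data"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

sim <- function(name, s, n_events = NULL, mode = NULL) {
  p <- preset(name, seed = s)
  if (!is.null(mode)) p$acquisition <- acquisition_config(mode = mode, seed = s)
  simulate_sample(p$mixture, p$acquisition, sample_id = name,
                  n_events = n_events)
}

movies <- c(
  list(calibrant_tg = sim("calibrant_tg", seed + 1L),
       calibrant_aav9e_start = sim("calibrant_aav9e", seed + 2L),
       calibrant_aav9e_end = sim("calibrant_aav9e", seed + 3L),
       mec_reference = sim("mec_reference", seed + 4L),
       mfc_reference = sim("mfc_reference", seed + 5L),
       harvest_mix_a = sim("harvest_mix_a", seed + 6L),
       harvest_mix_b = sim("harvest_mix_b", seed + 7L),
       aav8_extract = sim("aav8_extract", seed + 8L)),
  local({
    p <- preset("reference_aav9", seed = seed + 10L)
    reps <- simulate_replicates(p$mixture, p$acquisition, n_replicates = 5,
                                sample_id = "reference_aav9")
    names(reps) <- vapply(reps, `[[`, character(1), "sample_id")
    reps
  })
)

manifest <- lapply(names(movies), function(id) {
  path <- file.path(dir, paste0(id, ".csv"))
  write_event_csv(movies[[id]], path)
  list(sample_id = id, file = path, dilution_factor = 1)
})
write_manifest_yaml(manifest, file.path(dir, "manifest.yaml"))

counts <- vapply(movies, function(m) nrow(binding_events(m)), numeric(1))
cat(sprintf("wrote %d movies to %s (binding events: %d-%d, median %d)\n",
            length(movies), dir, min(counts), max(counts),
            as.integer(median(counts))))
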