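#!/usr/bin/env Rscript
# Stage 1: generate the synthetic seizure cohort.
#
# A 100-seizure catalog with bimodal log-durations (short ~10 s, long
# ~25 s populations), a shared decrease-then-increase connectivity motif on
# the in-going pyramidal connections, and an offset-linked excitation
# effect (pre-offset overshoot of alpha_ep grows with duration).  ECoG is
# simulated from the neural mass model at 400 Hz on the affected channel.
# Outputs: the annotation catalog, one example seizure's ECoG + ground
# truth, and the bundle manifest.

suppressPackageStartupMessages(library(seizurepath))

cfg <- reduced_study_config(seed = 1, link = 3)
cs <- cfg$catalog
cs$seed <- cfg$seed

message("Generating ", cs$n_seizures, " seizures at ", cs$fs, " Hz ...")
bundle <- generate_bundle(cs, motif = cfg$motif, link = cfg$link,
                          link_param = cfg$link_param)

dir.create("results", showWarnings = FALSE)
write_annotations(bundle$catalog, "results/catalog.csv")

dcomp <- table(bundle$catalog$component)
message(sprintf("Durations: %d short (median %.1f s), %d long (median %.1f s)",
                dcomp[1],
                median(bundle$catalog$duration[bundle$catalog$component == 1]),
                dcomp[2],
                median(bundle$catalog$duration[bundle$catalog$component == 2])))

# example seizure: ECoG and ground-truth trajectory side by side
ex <- bundle$seizures[[1]]
utils::write.csv(
  data.frame(time_s = ex$time, ecog_V = ex$segment$data[1, ],
             ex$true_theta, check.names = FALSE),
  "results/example_seizure.csv", row.names = FALSE)
message(sprintf("Example seizure: duration %.1f s, ECoG range [%.4f, %.4f] V",
                ex$duration, min(ex$segment$data), max(ex$segment$data)))
message("Wrote results/catalog.csv and results/example_seizure.csv")
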