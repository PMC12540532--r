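#!/usr/bin/env Rscript
# Simulate the study: 29 participants x 81 lifts of a 125 g and a 518 g cube
# in a transition-balanced pseudo-random order, recorded at 400 Hz by a
# handle transducer (half of total force) and a platform transducer
# (force reduction, truncated at lift-off).
#
# Writes: results/manifest.csv, results/sequence_p1.tsv, and one example
# trace per transition condition under results/traces/.

library(liftforce)

dir.create("results/traces", showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = 1)

cat("Simulating", cfg$n_participants, "participants,",
    4 * cfg$n_per_transition + 1, "lifts each...\n")
cohort <- simulate_cohort(cfg, keep_traces = FALSE, on_trial = function(rec) {
  # keep one example trace per (cube, switch) condition from participant 1
  if (rec$participant_id == 1 && rec$switch != "discard") {
    fname <- sprintf("results/traces/example_%s_%s.csv", rec$cube, rec$switch)
    if (!file.exists(fname)) write_trace(rec$trace, fname)
  }
  NULL
})

write_manifest(cohort, "results/manifest.csv")
write_sequence(
  vapply(cohort[seq_len(4 * cfg$n_per_transition + 1)], `[[`, character(1),
         "cube"),
  "results/sequence_p1.tsv")

lab <- do.call(rbind, lapply(cohort, function(r) {
  data.frame(cube = r$cube, switch = r$switch)
}))
cat("Total trials:", nrow(lab), "\n")
cat("Per condition (analyzable):\n")
print(table(lab$cube[lab$switch != "discard"],
            lab$switch[lab$switch != "discard"]))
cat("Wrote results/manifest.csv and example traces.\n")
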