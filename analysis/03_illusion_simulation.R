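#!/usr/bin/env Rscript
# Contact simulation of the full 3 x 3 stimulus grid (radii 4/6/8 mm,
# elasticities 10/50/90 kPa) at 0.25-2 N: cutaneous cue profiles at the
# epidermal-dermal interface, cue-distance matrices, illusion flags, and
# active-mode force-displacement (proprioceptive) curves.  Run at the coarse
# working resolution (56 interface nodes); expect ~10 minutes on one CPU.

library(tactillusion)
dir.create("results", showWarnings = FALSE)

cfg <- study_config() # full grid, loads 0.25/0.5/1/2 N
res <- run_experiment1(cfg, quiet = FALSE)

write.csv(res$profiles, "results/cue_profiles.csv", row.names = FALSE)
write.csv(res$distances, "results/cue_distances.csv", row.names = FALSE)
write.csv(res$illusion, "results/illusion_flags.csv", row.names = FALSE)
write.csv(res$fd_curves, "results/force_displacement.csv", row.names = FALSE)

cat("\nillusion flags (pair distance < distinct distance at every load):\n")
print(res$illusion)
if (length(res$failures)) {
  cat("solver failures:\n")
  print(unlist(res$failures))
}
sub <- subset(res$distances, load_N == 2 & cue == "stress" &
              a == "10kPa-4mm" & b %in% c("90kPa-8mm", "10kPa-8mm"))
cat("\ninterface-stress distances at 2 N from 10kPa-4mm:\n")
print(sub)
cat("\nfingertip displacement at 2 N (active):\n")
print(subset(res$fd_curves, force_N > 1.9))
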