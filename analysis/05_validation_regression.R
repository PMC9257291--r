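#!/usr/bin/env Rscript
# Stage 5: validate the manual (scorer-panel) species scores against the
# image-derived RMS contrast on the museum subset, with a phylogenetic
# random effect from the first candidate tree. On synthetic data both
# measures are driven by the same binary truth label, so the association
# should be strong and positive; the slope is on the manual-score scale per
# standard deviation of log RMS.

library(wingcontrast)

seed <- 20260920L
scores <- read.csv("scratch/species_scores.csv", stringsAsFactors = FALSE)
trees <- read_newick("scratch/data/trees.nwk")
tr <- match_tree_species(trees[[1]], scores$species_id, prune = TRUE)
V <- vcv_from_tree(tr)

vr <- validation_regression(scores$manual_score, scores$log_rms, V,
                            schedule = mcmc_schedule(15000, 1500, 10,
                                                     seed = seed),
                            species_id = scores$species_id)
out <- data.frame(n = nrow(scores), slope = vr$slope,
                  ci_lower = vr$slope_ci[1], ci_upper = vr$slope_ci[2],
                  pMCMC = vr$pMCMC, r_squared = vr$r_squared)
write.csv(out, "results/05_validation.csv", row.names = FALSE)

cat(sprintf("validation on %d museum species:\n", nrow(scores)))
cat(sprintf("  slope = %.3f (95%% HPD %.3f..%.3f, pMCMC = %.3g)\n",
            vr$slope, vr$slope_ci[1], vr$slope_ci[2], vr$pMCMC))
cat(sprintf("  Bayesian marginal R-squared = %.3f\n", vr$r_squared))
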