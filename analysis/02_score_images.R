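#!/usr/bin/env Rscript
# Stage 2: score the museum wing images two ways — RMS contrast of the
# masked, greyscaled image, and the 30-scorer manual count from the vote
# panel — then aggregate both to species level. Uniform (non-contrasting)
# wings legitimately have RMS 0 and are kept via the log(rms + 1e-6)
# convention, hence the warnings being suppressed here.

library(wingcontrast)

manifest <- read.csv("scratch/data/manifest.csv", stringsAsFactors = FALSE)
rms <- suppressWarnings(score_images(manifest, background = c(255, 0, 255)))
votes <- read_votes("scratch/data/votes.csv")
img_scores <- score_image(votes)
sp <- manifest$species_id[match(names(img_scores), manifest$image_id)]
manual <- score_species(img_scores, sp)

scores <- merge(manual, rms$species, by = "species_id")
write.csv(scores, "scratch/species_scores.csv", row.names = FALSE)

truth <- unlist(jsonlite::read_json("scratch/data/ground_truth.json")$image_truth)
truth <- truth[scores$species_id]
summary_tab <- data.frame(
  group = c("all", "truth_contrasting", "truth_uniform"),
  n = c(nrow(scores), sum(truth), sum(!truth)),
  mean_manual = c(mean(scores$manual_score),
                  mean(scores$manual_score[truth]),
                  mean(scores$manual_score[!truth])),
  mean_rms = c(mean(scores$rms), mean(scores$rms[truth]),
               mean(scores$rms[!truth])))
write.csv(summary_tab, "results/02_score_summary.csv", row.names = FALSE)

cat("Scored", nrow(manifest), "museum images\n")
print(summary_tab, row.names = FALSE, digits = 4)
cat(sprintf("manual score range: %d..%d of %d scorers\n",
            min(scores$manual_score), max(scores$manual_score), ncol(votes)))
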