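#!/usr/bin/env Rscript
# Simulate the field campaign: 10 framed scenes, 40 quadrats, half on the
# maize row, with grass / broadleaf / mixed / weed-free quadrats shuffled
# over the study. Writes the ground-truth table and one example scene.

library(weedvol)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

study <- generate_study(seed = 1)

write.csv(study$truth, "results/study_truth.csv", row.names = FALSE)

# one example scene as PLY (large; kept out of the versioned results)
write_mesh(study$scenes[[1]]$mesh, "scratch/example_scene.ply",
           binary = TRUE)

cat(sprintf("Simulated %d scenes (%d quadrats).\n",
            length(study$scenes), nrow(study$truth)))
cat("Weed cover composition:\n")
print(table(study$truth$weed_class))
cat(sprintf("True volumes: maize %.0f cm^3 total, weeds %.0f cm^3 total.\n",
            1e6 * sum(study$truth$true_maize_volume),
            1e6 * sum(study$truth$true_weed_volume)))
cat("Wrote results/study_truth.csv and scratch/example_scene.ply\n")
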