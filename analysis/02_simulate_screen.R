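#!/usr/bin/env Rscript
# Synthetic screen with known ground truth: latent binding effects for
# two baits (A ~ ABRAXAS1, B ~ CtIP) with critical/intermediate/neutral
# residue classes and the four validated separation-of-function
# injections, then multinomial pool counts for 3 replicates x 2
# conditions x 3 fragments per bait. Writes counts and the effect truth
# under results/screen/.

suppressMessages({
  library(satscreen)
  library(dplyr)
})

seed <- 20260924L
out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- screen_design()
effects <- draw_effects(design, effect_config(baits = c("A", "B")),
                        seed = seed)
counts <- simulate_counts(design, effects, depth_config(), seed = seed)

effects %>%
  filter(class == "missense") %>%
  group_by(bait) %>%
  summarise(dead = sum(b < 0.05), partial = sum(b >= 0.05 & b < 0.6),
            neutral = sum(b >= 0.6), .groups = "drop") %>%
  as.data.frame() %>%
  print()

totals <- counts %>%
  group_by(bait, replicate, condition, fragment) %>%
  summarise(N = sum(count), .groups = "drop")
message(sprintf("simulated %d samples of %d reads each",
                nrow(totals), unique(totals$N)))

readr::write_tsv(effects, file.path(out, "effects_truth.tsv"))
write_counts_tsv(counts, file.path(out, "counts.tsv"))
message("wrote ", out)
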