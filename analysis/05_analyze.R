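#!/usr/bin/env Rscript
# Downstream analysis: substitution heatmap matrices, per-residue
# aggregation with defattr export for structure mapping,
# separation-of-function classification of the two baits, and
# concordance with (synthetic) external annotations derived from the
# simulation truth. Writes under results/analysis/.

suppressMessages({
  library(satscreen)
  library(dplyr)
})

seed <- 20260924L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- screen_design()
effects <- readr::read_tsv("results/screen/effects_truth.tsv",
                           show_col_types = FALSE)
scores <- bind_rows(
  readr::read_tsv("results/scores/scores_A.tsv", show_col_types = FALSE),
  readr::read_tsv("results/scores/scores_B.tsv", show_col_types = FALSE)
)

## heatmap matrices and residue aggregation
for (bt in c("A", "B")) {
  m <- heatmap_matrix(scores, design, bait = bt)
  write_heatmap_tsv(m, file.path(out, sprintf("heatmap_%s.tsv", bt)))
  res <- residue_aggregate(scores, bait = bt)
  readr::write_tsv(res, file.path(out, sprintf("residue_%s.tsv", bt)))
  write_residue_attributes(res, paste0("bindingLoss_", bt),
                           file.path(out, sprintf("residue_%s.defattr", bt)))
  worst <- res %>% arrange(R_i) %>% head(5)
  message(sprintf("bait %s: most disruptive residues: %s", bt,
                  paste(sprintf("%d (%.0f)", worst$pos, worst$R_i),
                        collapse = ", ")))
}

## heatmap figure (bait A)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  m <- heatmap_matrix(scores, design, bait = "A")
  df <- as.data.frame(as.table(m$score)) |>
    setNames(c("pos", "aa", "score")) |>
    mutate(pos = as.integer(as.character(pos)),
           status = as.vector(m$status))
  p <- ggplot2::ggplot(df, ggplot2::aes(aa, pos, fill = score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "steelblue", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "substitution", y = "residue",
                  fill = "binding\nscore") +
    ggplot2::theme_minimal(base_size = 8)
  ggplot2::ggsave(file.path(out, "heatmap_A.png"), p,
                  width = 4, height = 9, dpi = 150)
}

## separation-of-function calls
sof <- classify_sof(scores, baits = c("A", "B"))
print(count(sof, sof_class))
inj <- default_sof_injections(c("A", "B")) %>% distinct(pos, alt)
message("injected SoF variants recovered as:")
print(sof %>% inner_join(inj, by = c("pos", "alt")) %>% as.data.frame())
readr::write_tsv(sof, file.path(out, "sof_calls.tsv"))

## concordance with synthetic external annotations
# numeric functionality-like annotation: noisy transform of the latent
# effect (min over baits), mimicking an independent functional assay
set.seed(seed)
truth <- effects %>%
  filter(class == "missense") %>%
  group_by(pos, wt, alt) %>%
  summarise(b_min = min(b), .groups = "drop")
num_ann <- truth %>%
  transmute(pos, alt,
            annotation = log(pmax(b_min, 1e-3)) + rnorm(n(), 0, 0.3))
ta <- filter(scores, bait == "A")
tb <- filter(scores, bait == "B")
conc_num <- external_concordance(ta, tb, num_ann)
print(conc_num)

# categorical clinical-style labels derived from the same truth (clearly
# synthetic; real analyses would join user-supplied classifications)
lab_ann <- truth %>%
  transmute(pos, alt, annotation = case_when(
    b_min < 0.05 ~ "pathogenic",
    b_min > 0.8 ~ "benign",
    TRUE ~ "VUS"
  ))
conc_lab <- external_concordance(ta, tb, lab_ann,
                                 group_pos = "pathogenic",
                                 group_neg = "benign")
print(conc_lab)
readr::write_tsv(conc_lab$vus_flagged, file.path(out, "vus_flagged.tsv"))
jsonlite::write_json(
  list(spearman = as.list(conc_num$spearman), auc = as.list(conc_lab$auc),
       n_vus_flagged = nrow(conc_lab$vus_flagged)),
  file.path(out, "concordance.json"), auto_unbox = TRUE, digits = NA)
message("wrote ", out)
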