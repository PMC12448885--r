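#!/usr/bin/env Rscript
# Library design: enumerate the site-saturation library over the default
# 214-residue domain (numbered 1646-1859), partition it into overlapping
# amplicon fragments under the 250-nt read limit, and lay out the
# marked-WT and stop-control spike-ins. Writes the serialized design and
# the variant manifest under results/design/.

suppressMessages({
  library(satscreen)
  library(dplyr)
})

out <- "results/design"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- screen_design()
print(design)

variants <- enumerate_variants(design$domain)
message(sprintf("library: %d unique missense variants (%d positions x 19)",
                nrow(variants), dplyr::n_distinct(variants$pos)))

message(sprintf(
  "fragmentation: %d fragments, %d-%d nt amplicons, minimum feasible = %d",
  nrow(design$fragments), min(design$fragments$nt_len),
  max(design$fragments$nt_len),
  satscreen:::min_fragments(design$domain$length, 4L, 250L)))

mk <- design$marked_wt$markers
message(sprintf("marked WT: %d synonymous markers (%d shifted off Met/Trp)",
                nrow(mk), sum(mk$shifted)))

write_design(design, out)
readr::write_tsv(variants, file.path(out, "variants.tsv"))
readr::write_tsv(design$fragments, file.path(out, "fragments.tsv"))
readr::write_tsv(mk, file.path(out, "markers.tsv"))
message("wrote ", out)
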