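#!/usr/bin/env Rscript
# Stage 3: functional-category over-representation and the first two
# consensus rules.
#
# Runs PageMan-style ORA (Fisher's exact test -> signed z, |z| > 1.96) on
# every contrast from stage 2, then:
#   - conserved categories: bins over-represented in the same direction in
#     all three germination time courses, with the interval where each hit
#     occurred and a timing-match flag for the two rice studies
#     (fig1_conserved.tsv)
#   - condition-specific categories: bins over-represented in the first
#     low-oxygen comparison AND a second, independent one, while never
#     over-represented under any abiotic stress (fig2_specific.tsv)

suppressPackageStartupMessages(library(lowoxmeta))

fix <- "results/fixtures"
de_dir <- "results/de"
out <- "results/ora"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ora_for <- function(de_file, bins, contrast) {
  de <- read_contrast_result(file.path(de_dir, de_file), contrast)
  run_ora(de, bins, background = de$gene, contrast_name = contrast)
}

## ---- germination trio: per-step ORA stacked per study ---------------------
bins_ath <- read_bin_annotation(file.path(fix, "germination/ath_bins.tsv"))
bins_osa <- read_bin_annotation(file.path(fix, "germination/osa_bins.tsv"))
steps <- c("2v1", "3v2", "4v3")
tc_ora <- list()
for (nm in c("ara_aero", "rice_aero", "rice_anae")) {
  bins <- if (nm == "ara_aero") bins_ath else bins_osa
  tabs <- lapply(steps, function(sp)
    ora_for(sprintf("%s_%s.tsv", nm, sp), bins, sub("v", " v ", sp)))
  tc_ora[[nm]] <- do.call(rbind, tabs)
  write_ora_result(tc_ora[[nm]], file.path(out, paste0(nm, "_ora.tsv")))
}
conserved <- rbind(
  conserved_categories(tc_ora, "up",
                       timing_pair = c("rice_aero", "rice_anae")),
  conserved_categories(tc_ora, "down",
                       timing_pair = c("rice_aero", "rice_anae")))
utils::write.table(conserved, file.path(out, "fig1_conserved.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("conserved categories: %d (timing match in rice: %s)",
                nrow(conserved),
                paste(conserved$bin[conserved$timing_match],
                      collapse = ", ")))

## ---- compendium ORA -------------------------------------------------------
bins_a <- read_bin_annotation(file.path(fix, "compendium/bins_a.tsv"))
bins_b <- read_bin_annotation(file.path(fix, "compendium/bins_b.tsv"))
comp_ora <- list()
for (f in list.files(de_dir, pattern = "^(lowox|abiotic)_", full.names = FALSE)) {
  nm <- sub("\\.tsv$", "", f)
  bins <- if (grepl("_a_", nm)) bins_a else bins_b
  comp_ora[[nm]] <- ora_for(f, bins, nm)
  write_ora_result(comp_ora[[nm]], file.path(out, paste0(nm, "_ora.tsv")))
}

## ---- condition-specific rule on the species-a comparisons -----------------
target <- comp_ora[["lowox_a_anoxia_1"]]
corequired <- comp_ora[["lowox_a_anoxia_2"]]
excluded <- comp_ora[grep("^abiotic_a_", names(comp_ora))]
specific <- rbind(
  data.frame(bin = condition_specific_categories(target, corequired,
                                                 excluded, "up"),
             direction = "up"),
  data.frame(bin = condition_specific_categories(target, corequired,
                                                 excluded, "down"),
             direction = "down"))
utils::write.table(specific, file.path(out, "fig2_specific.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("low-oxygen-specific categories: %d up, %d down",
                sum(specific$direction == "up"),
                sum(specific$direction == "down")))
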