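#!/usr/bin/env Rscript
# Stage 1: generate the synthetic fixtures every later stage consumes.
#
# Writes, under results/fixtures/:
#   single/      one replicated two-group study with detection calls and
#                planted 2-fold..64-fold responders (tests the DE stage)
#   germination/ three 4-timepoint germination-style time courses — one
#                "arabidopsis aerobic", one "rice aerobic", one "rice
#                anaerobic" — sharing a planted cohort of step responders
#                at the second interval, assigned to bin 25.1, so the
#                conserved-category and timing rules have a known answer
#   compendium/  the full two-species low-oxygen compendium: 4 rice-like
#                and 5 arabidopsis-like control-vs-low-oxygen comparisons,
#                abiotic-stress contrasts, bin annotations, two ortholog
#                evidence tables, and truth.json
#
# All randomness flows from the single SEED below.

suppressPackageStartupMessages(library(lowoxmeta))

SEED <- 1
fix <- "results/fixtures"
for (d in c("single", "germination", "compendium"))
  dir.create(file.path(fix, d), recursive = TRUE, showWarnings = FALSE)

## ---- single two-group study -----------------------------------------------
g <- generate_study(2000, de_fraction = 0.1, absent_fraction = 0.05,
                    study_id = "single", seed = SEED)
write_expression_study(g$study, file.path(fix, "single/matrix.tsv"),
                       file.path(fix, "single/design.tsv"))
write_presence_calls(g$calls, file.path(fix, "single/calls.tsv"))
write_truth(g$truth, file.path(fix, "single/truth.json"))
message(sprintf("single study: %d genes, %d planted DE, %d absent",
                length(g$study$genes), length(g$truth$planted_de[[1]]),
                length(g$truth$absent_genes)))

## ---- germination-style time courses ---------------------------------------
# a shared cohort of 30 step responders moves at the second interval (the
# "3 v 2" step-wise contrast) in all three studies; both rice studies use
# the same gene space, so the cohort is literally the same genes there
# (same interval -> timing match)
make_tc <- function(prefix, study_id, seed) {
  genes <- sprintf("%s_g%05d", prefix, 1:2000)
  responders <- setNames(runif(30, 2.5, 3.5), sprintf("g%05d", 101:130))
  tc <- generate_timecourse(2000, timepoints = 4, reps = 3,
                            step_responders = list(NULL, responders, NULL),
                            study_id = study_id, seed = seed)
  # generator gene ids are positional; relabel into the species gene space
  tc$study$genes <- genes
  rownames(tc$study$values) <- genes
  tc$truth$planted_de <- lapply(tc$truth$planted_de, function(e)
    setNames(e, genes[match(names(e), sprintf("g%05d", 1:2000))]))
  tc
}
set.seed(SEED)
tcs <- list(ara_aero = make_tc("ath", "ara_aero", SEED + 11),
            rice_aero = make_tc("osa", "rice_aero", SEED + 12),
            rice_anae = make_tc("osa", "rice_anae", SEED + 12 + 1000))
for (nm in names(tcs)) {
  write_expression_study(tcs[[nm]]$study,
                         file.path(fix, "germination", paste0(nm, "_matrix.tsv")),
                         file.path(fix, "germination", paste0(nm, "_design.tsv")))
  write_truth(tcs[[nm]]$truth,
              file.path(fix, "germination", paste0(nm, "_truth.json")))
}
# bin annotations: random background plus the responder cohort in 25.1
for (prefix in c("ath", "osa")) {
  genes <- sprintf("%s_g%05d", prefix, 1:2000)
  tab <- rbind(random_bin_annotation(genes,
                                     seed = SEED + 21 + (prefix == "osa")),
               data.frame(bin_path = "25.1",
                          bin_name = "germination program",
                          gene_id = genes[101:130]))
  write_bin_annotation(bin_annotation(tab),
                       file.path(fix, "germination",
                                 paste0(prefix, "_bins.tsv")))
}
message("germination trio: 3 studies x 4 timepoints, shared cohort in bin 25.1")

## ---- two-species compendium ------------------------------------------------
comp <- generate_species_pair(seed = SEED)
cdir <- file.path(fix, "compendium")
for (fam in c("lowox_a", "lowox_b", "abiotic_a", "abiotic_b")) {
  for (nm in names(comp[[fam]])) {
    stem <- file.path(cdir, paste0(fam, "_", nm))
    write_expression_study(comp[[fam]][[nm]], paste0(stem, "_matrix.tsv"),
                           paste0(stem, "_design.tsv"))
  }
}
write_bin_annotation(comp$bins_a, file.path(cdir, "bins_a.tsv"))
write_bin_annotation(comp$bins_b, file.path(cdir, "bins_b.tsv"))
utils::write.table(comp$ortho_sim, file.path(cdir, "orthologs_similarity.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(comp$ortho_inp, file.path(cdir, "orthologs_inparanoid.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_truth(comp$truth, file.path(cdir, "truth.json"))
message(sprintf("compendium: %d + %d low-oxygen comparisons, %d + %d abiotic, %d ortholog pairs",
                length(comp$lowox_a), length(comp$lowox_b),
                length(comp$abiotic_a), length(comp$abiotic_b),
                nrow(comp$truth$ortholog_classes)))
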