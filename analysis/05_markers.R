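#!/usr/bin/env Rscript
# Stage 5: low-oxygen marker genes.
#
# Applies the marker rule per species: called up with a linear fold-change
# above 50 in a quorum of the low-oxygen comparisons (2 of 4 for species a,
# 3 of 5 for species b), with genes up-regulated under any abiotic stress
# excluded for species a. Writes table2_markers.tsv and checks the result
# against the planted truth.

suppressPackageStartupMessages(library(lowoxmeta))

fix <- "results/fixtures"
de_dir <- "results/de"
out <- "results/meta"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

member <- function(stem)
  list(study_id = stem, contrast = stem,
       de = read_contrast_result(file.path(de_dir, paste0(stem, ".tsv")),
                                 stem))
stems <- function(pattern)
  sub("\\.tsv$", "", list.files(de_dir, pattern = pattern))

markers_a <- find_marker_genes(
  study_set("a lowox", lapply(stems("^lowox_a_"), member)),
  fold_min = 50, k_min = 2,
  abiotic = study_set("a abiotic", lapply(stems("^abiotic_a_"), member)),
  exclude_abiotic_up = TRUE)
markers_b <- find_marker_genes(
  study_set("b lowox", lapply(stems("^lowox_b_"), member)),
  fold_min = 50, k_min = 3,
  abiotic = study_set("b abiotic", lapply(stems("^abiotic_b_"), member)),
  exclude_abiotic_up = FALSE)

tab <- rbind(data.frame(species = rep("a", nrow(markers_a)), markers_a),
             data.frame(species = rep("b", nrow(markers_b)), markers_b))
utils::write.table(tab, file.path(out, "table2_markers.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(file.path(fix, "compendium/truth.json"),
                             simplifyVector = TRUE)
message(sprintf("species a markers: %s", paste(markers_a$gene, collapse = ", ")))
message(sprintf("planted          : %s",
                paste(truth$planted_markers, collapse = ", ")))
message(sprintf("exact recovery: %s; species b markers: %d (none planted)",
                setequal(markers_a$gene, truth$planted_markers),
                nrow(markers_b)))
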