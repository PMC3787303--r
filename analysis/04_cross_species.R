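#!/usr/bin/env Rscript
# Stage 4: cross-species consensus, stress overlap, ortholog projection.
#
#   - species consensus at the 3-of-4 / 4-of-5 quorums over the low-oxygen
#     ORA tables of both species (fig3_species.tsv)
#   - overlap counts between each low-oxygen comparison's DE genes and each
#     abiotic-stress contrast's, in both counting modes (fig4_overlap_*.tsv)
#   - projection of the species-a genes with orthologs onto the species-b
#     contrasts through the union ortholog map (fig4_projection.tsv)

suppressPackageStartupMessages(library(lowoxmeta))

fix <- "results/fixtures"
de_dir <- "results/de"
ora_dir <- "results/ora"
out <- "results/meta"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

member <- function(stem) {
  list(study_id = stem, contrast = stem,
       ora = read_ora_result(file.path(ora_dir, paste0(stem, "_ora.tsv"))),
       de = read_contrast_result(file.path(de_dir, paste0(stem, ".tsv")),
                                 stem))
}
stems <- function(pattern)
  sub("\\.tsv$", "", list.files(de_dir, pattern = pattern))
sets <- list(
  lowox_a = study_set("species-a low-oxygen",
                      lapply(stems("^lowox_a_"), member)),
  lowox_b = study_set("species-b low-oxygen",
                      lapply(stems("^lowox_b_"), member)),
  abiotic_a = study_set("species-a abiotic",
                        lapply(stems("^abiotic_a_"), member)),
  abiotic_b = study_set("species-b abiotic",
                        lapply(stems("^abiotic_b_"), member)))

## ---- species consensus ----------------------------------------------------
consensus <- rbind(
  species_consensus(sets$lowox_a, sets$lowox_b, k_a = 3, k_b = 4, "up"),
  species_consensus(sets$lowox_a, sets$lowox_b, k_a = 3, k_b = 4, "down"))
utils::write.table(consensus, file.path(out, "fig3_species.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (cl in c("a_only", "b_only", "both"))
  message(sprintf("%-8s: %s", cl,
                  paste(consensus$bin[consensus$class == cl],
                        collapse = ", ")))

## ---- low-oxygen x abiotic overlap counts ----------------------------------
for (sp in c("a", "b")) for (mode in c("any_direction", "matched")) {
  m <- overlap_counts(sets[[paste0("lowox_", sp)]],
                      sets[[paste0("abiotic_", sp)]], mode)
  utils::write.table(data.frame(contrast = rownames(m), m,
                                check.names = FALSE),
                     file.path(out, sprintf("fig4_overlap_%s_%s.tsv", sp,
                                            mode)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
message("overlap matrices written for both species and both modes")

## ---- ortholog union and projection ----------------------------------------
map <- union_orthologs(
  read_ortholog_table(file.path(fix, "compendium/orthologs_similarity.tsv")),
  read_ortholog_table(file.path(fix, "compendium/orthologs_inparanoid.tsv")),
  species_a = "species_a", species_b = "species_b")
print(map)
write_ortholog_map(map, file.path(out, "ortholog_map.tsv"))

foreign <- lapply(sets$lowox_b$members, function(m) m$de)
names(foreign) <- vapply(sets$lowox_b$members, function(m) m$contrast, "")
proj <- project_contrasts(unique(map$pairs$gene_a), map, foreign)
utils::write.table(proj, file.path(out, "fig4_projection.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
# tally conservation seen in the first foreign contrast
first_call <- proj[[paste0(names(foreign)[1], ".call")]]
message(sprintf("projection: %d (gene, ortholog) rows; partner calls in %s: %s",
                nrow(proj), names(foreign)[1],
                paste(names(table(first_call)), table(first_call),
                      sep = "=", collapse = ", ")))
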