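#' Run the full cross-species low-oxygen analysis on a compendium
#'
#' Executes every stage on a two-species compendium as produced by
#' [generate_species_pair()] (or assembled from files): per-comparison
#' regularized differential expression with mixture-model PPDE and the
#' three-part call, per-comparison over-representation analysis of the
#' functional bins, ortholog union mapping, species-consensus
#' classification of categories, low-oxygen/abiotic overlap counting, and
#' marker-gene identification with the species-a abiotic exclusion.
#'
#' @param comp compendium list with elements `lowox_a`, `lowox_b`,
#'   `abiotic_a`, `abiotic_b` (named lists of two-condition
#'   ExpressionStudy), `bins_a`, `bins_b`, `ortho_sim`, `ortho_inp`,
#'   `species_a`, `species_b`.
#' @param params CyberTParams for the regularized t-test.
#' @param fold_threshold,p_threshold,ppde_threshold DE call thresholds.
#' @param z_threshold ORA significance threshold on |z|.
#' @param k_a,k_b species-specific consensus quorums (defaults 3 of the four
#'   species-a and 4 of the five species-b comparisons).
#' @param marker_fold,marker_k_a,marker_k_b marker rule: linear fold
#'   threshold and per-species minimum passing comparisons (defaults 50,
#'   2, 3).
#' @param exclude_abiotic_a,exclude_abiotic_b apply the abiotic up-exclusion
#'   per species (defaults TRUE for a, FALSE for b, mirroring the
#'   asymmetric marker definitions).
#' @return list with per-comparison `de_*` and `ora_*` tables, `sets`
#'   (StudySet per species and stress family), `ortho_map`, `consensus`
#'   (up and down species-consensus tables), `overlap` (per species, both
#'   modes), and `markers` (per species).
#' @export
run_lowox_pipeline <- function(comp, params = cybert_params(),
                               fold_threshold = 2, p_threshold = 0.05,
                               ppde_threshold = 0.96, z_threshold = 1.96,
                               k_a = 3, k_b = 4,
                               marker_fold = 50, marker_k_a = 2,
                               marker_k_b = 3,
                               exclude_abiotic_a = TRUE,
                               exclude_abiotic_b = FALSE) {
  run_family <- function(studies, bins) {
    de <- list(); ora <- list()
    for (nm in names(studies)) {
      st <- studies[[nm]]
      conds <- unique(st$design$condition)
      spec <- contrast_spec(st$study_id, nm,
                            group_a = condition_samples(st, conds[1]),
                            group_b = condition_samples(st, conds[2]))
      de[[nm]] <- run_contrast(st, spec, params, fold_threshold,
                               p_threshold, ppde_threshold)
      ora[[nm]] <- run_ora(de[[nm]], bins, background = st$genes,
                           z_threshold = z_threshold, contrast_name = nm)
    }
    list(de = de, ora = ora)
  }
  fam_a <- run_family(comp$lowox_a, comp$bins_a)
  fam_b <- run_family(comp$lowox_b, comp$bins_b)
  fam_abio_a <- run_family(comp$abiotic_a, comp$bins_a)
  fam_abio_b <- run_family(comp$abiotic_b, comp$bins_b)

  members <- function(fam) lapply(names(fam$de), function(nm)
    list(study_id = attr(fam$de[[nm]], "contrast")$study_id,
         contrast = nm, ora = fam$ora[[nm]], de = fam$de[[nm]]))
  sets <- list(
    lowox_a = study_set(paste(comp$species_a, "low-oxygen"),
                        members(fam_a)),
    lowox_b = study_set(paste(comp$species_b, "low-oxygen"),
                        members(fam_b)),
    abiotic_a = study_set(paste(comp$species_a, "abiotic"),
                          members(fam_abio_a)),
    abiotic_b = study_set(paste(comp$species_b, "abiotic"),
                          members(fam_abio_b)))

  ortho_map <- union_orthologs(comp$ortho_sim, comp$ortho_inp,
                               species_a = comp$species_a,
                               species_b = comp$species_b)

  consensus <- list(
    up = species_consensus(sets$lowox_a, sets$lowox_b, k_a, k_b, "up"),
    down = species_consensus(sets$lowox_a, sets$lowox_b, k_a, k_b, "down"))

  overlap <- list(
    a = list(any = overlap_counts(sets$lowox_a, sets$abiotic_a,
                                  "any_direction"),
             matched = overlap_counts(sets$lowox_a, sets$abiotic_a,
                                      "matched")),
    b = list(any = overlap_counts(sets$lowox_b, sets$abiotic_b,
                                  "any_direction"),
             matched = overlap_counts(sets$lowox_b, sets$abiotic_b,
                                      "matched")))

  markers <- list(
    a = find_marker_genes(sets$lowox_a, marker_fold, marker_k_a,
                          abiotic = sets$abiotic_a,
                          exclude_abiotic_up = exclude_abiotic_a),
    b = find_marker_genes(sets$lowox_b, marker_fold, marker_k_b,
                          abiotic = sets$abiotic_b,
                          exclude_abiotic_up = exclude_abiotic_b))

  list(de_a = fam_a$de, de_b = fam_b$de,
       ora_a = fam_a$ora, ora_b = fam_b$ora,
       de_abiotic_a = fam_abio_a$de, de_abiotic_b = fam_abio_b$de,
       sets = sets, ortho_map = ortho_map, consensus = consensus,
       overlap = overlap, markers = markers)
}
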