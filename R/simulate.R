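#' @name simulate
#' @title Synthetic studies with planted ground truth
#' @description
#' Generators for synthetic expression studies that emulate the data the
#' pipeline is designed for: log2-scale replicated intensities with Gaussian
#' replicate noise around per-gene baselines, planted up/down-regulated
#' genes spanning 2-fold to >100-fold, multi-timepoint designs with
#' step-responders, and a two-species compendium with planted ortholog
#' conservation classes, enriched functional bins and marker genes. Every
#' generator is deterministic given its seed and returns a machine-readable
#' truth object, so each pipeline stage can be tested by recovery of what
#' was planted.
NULL

# deterministic sub-seed derivation so nested generators draw independent,
# reproducible streams from one top-level seed (kept below 2^31)
sub_seed <- function(seed, i) {
  (as.numeric(seed) * 97 + i * 1009) %% 2147483629 + 1
}

#' Generate a replicated two-group study
#'
#' Per-gene baselines are drawn once from Normal(`baseline_mean`,
#' `baseline_sd`); each replicate value is baseline + condition effect +
#' Normal(0, `noise_sd`). A fraction `de_fraction` of genes receive a
#' planted log2 effect drawn uniformly from plus or minus `effect_range`,
#' applied to every non-reference condition. Detection calls are present
#' everywhere except for `absent_fraction` of genes, which are absent in
#' all samples.
#'
#' @param n_genes number of genes (>= 100 recommended so the downstream
#'   mixture fit is stable).
#' @param conditions character vector of condition labels; the first is the
#'   reference.
#' @param reps replicates per condition.
#' @param de_fraction proportion of genes with a planted effect.
#' @param effect_range log2 interval for planted effect magnitudes
#'   (default 1 to 6, i.e. 2-fold to 64-fold).
#' @param noise_sd replicate noise sd on the log2 scale (default 0.25).
#' @param baseline_mean,baseline_sd baseline distribution (default 8 and 2).
#' @param absent_fraction proportion of genes called absent in all samples.
#' @param study_id study label.
#' @param seed integer seed; identical inputs reproduce identical outputs.
#' @return list with `study` (ExpressionStudy), `calls` (PresenceCalls) and
#'   `truth` (list: `planted_de` mapping contrast name -> named effect
#'   vector, `absent_genes`, `seed`).
#' @export
generate_study <- function(n_genes, conditions = c("control", "treatment"),
                           reps = 3, de_fraction = 0.1,
                           effect_range = c(1, 6), noise_sd = 0.25,
                           baseline_mean = 8, baseline_sd = 2,
                           absent_fraction = 0, study_id = "synthetic",
                           seed = 1) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  if (length(conditions) < 2L) stop("need >= 2 conditions")
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_de <- round(de_fraction * n_genes)
  de_genes <- sort(sample(genes, n_de))
  effects <- stats::setNames(rep(0, n_genes), genes)
  if (n_de > 0)
    effects[de_genes] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, effect_range[1], effect_range[2])

  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  samples <- as.vector(t(outer(conditions, seq_len(reps),
                               function(c, r) paste0(c, "_r", r))))
  design <- data.frame(sample = samples,
                       condition = rep(conditions, each = reps),
                       timepoint = NA_integer_,
                       replicate = rep(seq_len(reps), length(conditions)),
                       stringsAsFactors = FALSE)
  values <- matrix(0, n_genes, length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    eff <- if (design$condition[j] == conditions[1]) 0 else effects
    values[, j] <- baseline + eff + stats::rnorm(n_genes, 0, noise_sd)
  }
  study <- expression_study(study_id, values, design)

  n_absent <- round(absent_fraction * n_genes)
  absent <- if (n_absent > 0) sort(sample(genes, n_absent)) else character()
  dp <- matrix(stats::runif(n_genes * length(samples), 0, 0.045),
               n_genes, length(samples), dimnames = dimnames(values))
  if (length(absent))
    dp[absent, ] <- stats::runif(length(absent) * length(samples), 0.07, 1)
  calls <- presence_calls(dp)

  planted <- lapply(conditions[-1], function(cc)
    effects[de_genes])
  names(planted) <- paste(conditions[-1], "v", conditions[1])
  list(study = study, calls = calls,
       truth = list(planted_de = planted, absent_genes = absent,
                    seed = seed))
}

#' Generate a time-course study with planted step responders
#'
#' Expression follows a per-gene step function over `timepoints` ranks: a
#' responder planted at interval i changes by its effect between timepoint i
#' and i+1 and stays at the new level, so the step-wise contrast of that
#' interval (and only that one) sees the change. Profiles are otherwise
#' flat.
#'
#' @param n_genes number of genes.
#' @param timepoints number of timepoint ranks (>= 2).
#' @param reps replicates per timepoint.
#' @param step_responders list of length `timepoints - 1`; element i is
#'   either `NULL`, an integer count of responders to sample (log2 effects
#'   drawn uniformly from plus/minus 2 to 4), or a named numeric vector of
#'   gene -> log2 effect.
#' @param noise_sd,baseline_mean,baseline_sd as in [generate_study()].
#' @param condition condition label of the series.
#' @param study_id study label.
#' @param seed integer seed.
#' @return list with `study` and `truth` (`planted_de` mapping step-wise
#'   contrast name -> named effect vector, `seed`).
#' @export
generate_timecourse <- function(n_genes, timepoints = 4, reps = 3,
                                step_responders = vector("list", timepoints - 1),
                                noise_sd = 0.25, baseline_mean = 8,
                                baseline_sd = 2,
                                condition = "timecourse",
                                study_id = "synthetic_timecourse",
                                seed = 1) {
  if (timepoints < 2L) stop("need >= 2 timepoints")
  if (length(step_responders) != timepoints - 1L)
    stop("step_responders must have one element per interval (",
         timepoints - 1L, ")")
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  used <- character()
  eff_by_interval <- vector("list", timepoints - 1L)
  for (i in seq_len(timepoints - 1L)) {
    sr <- step_responders[[i]]
    if (is.null(sr)) {
      eff_by_interval[[i]] <- stats::setNames(numeric(), character())
    } else if (is.numeric(sr) && is.null(names(sr)) && length(sr) == 1L) {
      pick <- sample(setdiff(genes, used), sr)
      eff_by_interval[[i]] <- stats::setNames(
        sample(c(-1, 1), sr, replace = TRUE) * stats::runif(sr, 2, 4), pick)
    } else {
      bad <- setdiff(names(sr), genes)
      if (length(bad)) stop("unknown responder gene(s): ",
                            paste(bad, collapse = ", "))
      eff_by_interval[[i]] <- sr
    }
    used <- c(used, names(eff_by_interval[[i]]))
  }

  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  level <- matrix(rep(baseline, timepoints), n_genes, timepoints,
                  dimnames = list(genes, NULL))
  for (i in seq_len(timepoints - 1L)) {
    e <- eff_by_interval[[i]]
    if (length(e))
      level[names(e), (i + 1L):timepoints] <-
        level[names(e), (i + 1L):timepoints, drop = FALSE] + e
  }

  samples <- as.vector(outer(seq_len(reps), seq_len(timepoints),
                             function(r, t) sprintf("t%d_r%d", t, r)))
  design <- data.frame(sample = samples,
                       condition = condition,
                       timepoint = rep(seq_len(timepoints), each = reps),
                       replicate = rep(seq_len(reps), timepoints),
                       stringsAsFactors = FALSE)
  values <- matrix(0, n_genes, length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples))
    values[, j] <- level[, design$timepoint[j]] +
      stats::rnorm(n_genes, 0, noise_sd)
  study <- expression_study(study_id, values, design)

  planted <- eff_by_interval
  names(planted) <- sprintf("%d v %d", 2:timepoints, 1:(timepoints - 1L))
  list(study = study,
       truth = list(planted_de = planted, seed = seed))
}

#' Random 2-level bin annotation
#'
#' Assigns each gene to 1-3 leaves of a two-level hierarchy (`n_top`
#' top-level bins with two children each); leaf selection probabilities are
#' log-uniform so realized bin sizes span roughly 10-200 genes at 2000
#' genes. Returned as the assignment data.frame accepted by
#' [bin_annotation()], so planted rows can be appended before construction.
#'
#' @param genes character vector of gene ids.
#' @param n_top number of top-level bins (default 10).
#' @param seed integer seed.
#' @return data.frame with columns `bin_path`, `bin_name`, `gene_id`.
#' @export
random_bin_annotation <- function(genes, n_top = 10, seed = 1) {
  set.seed(seed)
  leaves <- as.vector(outer(seq_len(n_top), 1:2,
                            function(i, j) paste(i, j, sep = ".")))
  w <- exp(stats::runif(length(leaves), log(10), log(200)))
  w <- w / sum(w)
  rows <- lapply(genes, function(g) {
    k <- sample(1:3, 1)
    data.frame(bin_path = sample(leaves, k, prob = w),
               bin_name = NA_character_, gene_id = g,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$bin_name <- paste("bin", tab$bin_path)
  tab
}

make_two_group_study <- function(study_id, genes, effects, reps, noise_sd,
                                 baseline_mean, baseline_sd, seed,
                                 conditions = c("control", "lowox")) {
  set.seed(seed)
  n_genes <- length(genes)
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  samples <- as.vector(t(outer(conditions, seq_len(reps),
                               function(c, r) paste0(c, "_r", r))))
  design <- data.frame(sample = samples,
                       condition = rep(conditions, each = reps),
                       timepoint = NA_integer_,
                       replicate = rep(seq_len(reps), length(conditions)),
                       stringsAsFactors = FALSE)
  eff <- stats::setNames(rep(0, n_genes), genes)
  eff[names(effects)] <- effects
  values <- matrix(0, n_genes, length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    e <- if (design$condition[j] == conditions[1]) 0 else eff
    values[, j] <- baseline + e + stats::rnorm(n_genes, 0, noise_sd)
  }
  expression_study(study_id, values, design)
}

#' Generate a two-species low-oxygen compendium with planted truth
#'
#' Builds the full cross-species test bed: several independent low-oxygen
#' comparisons per species (each a control-vs-low-oxygen study over a shared
#' per-species gene set), abiotic-stress contrasts, per-species functional
#' bin annotations, and two overlapping ortholog evidence tables whose union
#' is the complete planted pair set. Planted structure:
#' \itemize{
#'   \item ortholog pairs carry conservation classes — `conserved_up` /
#'     `conserved_down` (same-sign effects in both species), `divergent`
#'     (responds in species a only), `opposite` (up in a, down in b),
#'     `unrelated` (no response);
#'   \item conserved enriched bins whose member genes are up-regulated in
#'     every comparison of both species;
#'   \item one species-a-only bin (up in `quorum_a` of the a comparisons,
#'     never in b) and one species-b-only bin (up in `quorum_b` of the b
#'     comparisons, never in a);
#'   \item marker genes induced >100-fold (log2 effects 6-7) in
#'     `marker_comparisons` of the species-a comparisons and untouched by
#'     abiotic stress, alongside decoys that fail exactly one marker rule:
#'     strong induction but also up under an abiotic stress, and broad
#'     induction below the 50-fold bar.
#' }
#' Background differential expression (log2 effects 1-5, both signs) is
#' shared across a species' low-oxygen comparisons; abiotic contrasts draw
#' independent background responders.
#'
#' @param n_genes genes per species.
#' @param n_comparisons_a,n_comparisons_b low-oxygen comparisons per species
#'   (defaults 4 and 5).
#' @param n_abiotic abiotic-stress contrasts per species (default 4:
#'   cold, drought, salt, heat).
#' @param reps replicates per group.
#' @param n_ortholog_pairs planted ortholog pairs.
#' @param class_mix named proportions over the five conservation classes
#'   (must sum to 1).
#' @param n_conserved_bins planted conserved bins (default 2).
#' @param bin_size genes per planted bin (default 30).
#' @param quorum_a,quorum_b comparisons in which the species-specific bins
#'   respond (defaults 3 and 4).
#' @param n_markers planted marker genes in species a (default 5).
#' @param marker_comparisons comparisons in which markers respond
#'   (default 3).
#' @param de_fraction background DE fraction per species.
#' @param noise_sd,baseline_mean,baseline_sd as in [generate_study()].
#' @param species_a,species_b species labels.
#' @param seed integer seed.
#' @return list with `species_a`, `species_b`, `lowox_a`, `lowox_b`,
#'   `abiotic_a`, `abiotic_b` (each a named list of ExpressionStudy),
#'   `bins_a`, `bins_b` (BinAnnotation), `ortho_sim`, `ortho_inp`
#'   (pair tables) and `truth`.
#' @export
generate_species_pair <- function(n_genes = 2000,
                                  n_comparisons_a = 4, n_comparisons_b = 5,
                                  n_abiotic = 4, reps = 3,
                                  n_ortholog_pairs = 300,
                                  class_mix = c(conserved_up = 0.3,
                                                conserved_down = 0.2,
                                                divergent = 0.2,
                                                opposite = 0.1,
                                                unrelated = 0.2),
                                  n_conserved_bins = 2, bin_size = 30,
                                  quorum_a = 3, quorum_b = 4,
                                  n_markers = 5, marker_comparisons = 3,
                                  de_fraction = 0.1, noise_sd = 0.25,
                                  baseline_mean = 8, baseline_sd = 2,
                                  species_a = "rice",
                                  species_b = "arabidopsis",
                                  seed = 1) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  classes <- c("conserved_up", "conserved_down", "divergent", "opposite",
               "unrelated")
  if (!all(names(class_mix) %in% classes))
    stop("unknown ortholog class in class_mix")
  set.seed(sub_seed(seed, 0))

  genes_a <- sprintf("osa_g%05d", seq_len(n_genes))
  genes_b <- sprintf("ath_g%05d", seq_len(n_genes))

  # ---- ortholog pairs and conservation classes
  counts <- round(class_mix * n_ortholog_pairs)
  counts[1] <- n_ortholog_pairs - sum(counts[-1])
  cls <- sample(rep(names(counts), counts))
  pair_idx <- seq_len(n_ortholog_pairs)
  pairs <- data.frame(gene_a = genes_a[pair_idx], gene_b = genes_b[pair_idx],
                      class = cls, stringsAsFactors = FALSE)
  mag <- stats::runif(n_ortholog_pairs, 1.5, 3.5)
  eff_a <- ifelse(cls == "conserved_down", -mag,
                  ifelse(cls == "unrelated", 0, mag))
  eff_b <- ifelse(cls == "conserved_up", mag,
                  ifelse(cls == "conserved_down", -mag,
                         ifelse(cls == "opposite", -mag, 0)))

  # ---- reserve special genes outside the pair block
  pool <- (n_ortholog_pairs + 1L):n_genes
  take <- function(n) {
    idx <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    idx
  }
  conserved_bin_genes_a <- replicate(n_conserved_bins, take(bin_size),
                                     simplify = FALSE)
  conserved_bin_genes_b <- replicate(n_conserved_bins, take(bin_size),
                                     simplify = FALSE)
  a_only_genes <- take(bin_size)
  b_only_genes <- take(bin_size)
  a_only_decoy_b <- take(bin_size)   # same bin in species b, non-responding
  b_only_decoy_a <- take(bin_size)
  marker_idx <- take(n_markers)
  decoy_abiotic_idx <- take(2)       # >50-fold but also abiotic-induced
  decoy_fold_idx <- take(2)          # broad induction below 50-fold

  # ---- background DE per species (shared across a species' comparisons)
  bg_pool <- pool
  n_bg <- round(de_fraction * n_genes)
  bg_a <- sample(bg_pool, n_bg)
  bg_b <- sample(bg_pool, n_bg)
  bg_eff_a <- sample(c(-1, 1), n_bg, TRUE) * stats::runif(n_bg, 1, 5)
  bg_eff_b <- sample(c(-1, 1), n_bg, TRUE) * stats::runif(n_bg, 1, 5)

  conserved_eff_a <- lapply(conserved_bin_genes_a, function(idx)
    stats::setNames(stats::runif(length(idx), 2, 4), genes_a[idx]))
  conserved_eff_b <- lapply(conserved_bin_genes_b, function(idx)
    stats::setNames(stats::runif(length(idx), 2, 4), genes_b[idx]))
  a_only_eff <- stats::setNames(stats::runif(bin_size, 2, 4),
                                genes_a[a_only_genes])
  b_only_eff <- stats::setNames(stats::runif(bin_size, 2, 4),
                                genes_b[b_only_genes])
  marker_eff <- stats::setNames(stats::runif(n_markers, 6, 7),
                                genes_a[marker_idx])
  decoy_abiotic_eff <- stats::setNames(stats::runif(2, 6, 7),
                                       genes_a[decoy_abiotic_idx])
  decoy_fold_eff <- stats::setNames(stats::runif(2, 4.5, 5.0),
                                    genes_a[decoy_fold_idx])

  # per-comparison effect vectors
  effects_for_a <- function(i) {
    e <- stats::setNames(rep(0, n_genes), genes_a)
    e[pairs$gene_a] <- eff_a
    e[genes_a[bg_a]] <- bg_eff_a
    for (ce in conserved_eff_a) e[names(ce)] <- ce
    if (i <= quorum_a) e[names(a_only_eff)] <- a_only_eff
    if (i <= marker_comparisons) {
      e[names(marker_eff)] <- marker_eff
      e[names(decoy_abiotic_eff)] <- decoy_abiotic_eff
    }
    e[names(decoy_fold_eff)] <- decoy_fold_eff
    e[e != 0]
  }
  effects_for_b <- function(i) {
    e <- stats::setNames(rep(0, n_genes), genes_b)
    e[pairs$gene_b] <- eff_b
    e[genes_b[bg_b]] <- bg_eff_b
    for (ce in conserved_eff_b) e[names(ce)] <- ce
    if (i <= quorum_b) e[names(b_only_eff)] <- b_only_eff
    e[e != 0]
  }

  lowox_a <- lapply(seq_len(n_comparisons_a), function(i)
    make_two_group_study(sprintf("%s_lowox_%d", species_a, i), genes_a,
                         effects_for_a(i), reps, noise_sd, baseline_mean,
                         baseline_sd, sub_seed(seed, 10 + i)))
  names(lowox_a) <- sprintf("anoxia_%d", seq_len(n_comparisons_a))
  lowox_b <- lapply(seq_len(n_comparisons_b), function(i)
    make_two_group_study(sprintf("%s_lowox_%d", species_b, i), genes_b,
                         effects_for_b(i), reps, noise_sd, baseline_mean,
                         baseline_sd, sub_seed(seed, 30 + i)))
  names(lowox_b) <- sprintf("hypoxia_%d", seq_len(n_comparisons_b))

  # ---- abiotic-stress contrasts (independent background responders)
  stresses <- c("cold", "drought", "salt", "heat")[seq_len(n_abiotic)]
  abiotic_one <- function(genes, sp, i, extra_up = NULL) {
    set.seed(sub_seed(seed, 50 + 10 * (sp == species_b) + i))
    idx <- sample(bg_pool, n_bg)
    e <- stats::setNames(sample(c(-1, 1), n_bg, TRUE) *
                           stats::runif(n_bg, 1, 4), genes[idx])
    if (!is.null(extra_up)) e[names(extra_up)] <- extra_up
    make_two_group_study(sprintf("%s_%s", sp, stresses[i]), genes, e, reps,
                         noise_sd, baseline_mean, baseline_sd,
                         sub_seed(seed, 70 + 10 * (sp == species_b) + i),
                         conditions = c("control", "stress"))
  }
  # abiotic decoys: strongly low-oxygen-induced genes also up under the
  # first abiotic stress, so the marker exclusion rule has work to do
  abiotic_a <- lapply(seq_len(n_abiotic), function(i)
    abiotic_one(genes_a, species_a, i,
                extra_up = if (i == 1L)
                  stats::setNames(rep(2.5, 2), names(decoy_abiotic_eff))))
  names(abiotic_a) <- stresses
  abiotic_b <- lapply(seq_len(n_abiotic), function(i)
    abiotic_one(genes_b, species_b, i))
  names(abiotic_b) <- stresses

  # ---- bin annotations with planted bins
  base_bins_a <- random_bin_annotation(genes_a, seed = sub_seed(seed, 90))
  base_bins_b <- random_bin_annotation(genes_b, seed = sub_seed(seed, 91))
  planted_rows <- function(path, name, genes) {
    data.frame(bin_path = path, bin_name = name, gene_id = genes,
               stringsAsFactors = FALSE)
  }
  conserved_paths <- sprintf("25.%d", seq_len(n_conserved_bins))
  extra_a <- do.call(rbind, c(
    lapply(seq_len(n_conserved_bins), function(i)
      planted_rows(conserved_paths[i], paste("conserved bin", i),
                   genes_a[conserved_bin_genes_a[[i]]])),
    list(planted_rows("26.1", "species-a-only bin", genes_a[a_only_genes]),
         planted_rows("27.1", "species-b-only bin",
                      genes_a[b_only_decoy_a]))))
  extra_b <- do.call(rbind, c(
    lapply(seq_len(n_conserved_bins), function(i)
      planted_rows(conserved_paths[i], paste("conserved bin", i),
                   genes_b[conserved_bin_genes_b[[i]]])),
    list(planted_rows("26.1", "species-a-only bin",
                      genes_b[a_only_decoy_b]),
         planted_rows("27.1", "species-b-only bin",
                      genes_b[b_only_genes]))))
  bins_a <- bin_annotation(rbind(base_bins_a, extra_a))
  bins_b <- bin_annotation(rbind(base_bins_b, extra_b))

  # ---- two overlapping ortholog evidence tables covering the union
  set.seed(sub_seed(seed, 95))
  src <- sample(c("both", "sim", "inp"), n_ortholog_pairs, TRUE,
                prob = c(0.6, 0.2, 0.2))
  pct <- round(stats::runif(n_ortholog_pairs, 40, 95), 1)
  ortho_sim <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                          pct_identity = pct,
                          stringsAsFactors = FALSE)[src != "inp", ]
  ortho_inp <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                          stringsAsFactors = FALSE)[src != "sim", ]
  rownames(ortho_sim) <- rownames(ortho_inp) <- NULL

  planted_de_a <- lapply(seq_len(n_comparisons_a), effects_for_a)
  names(planted_de_a) <- names(lowox_a)
  planted_de_b <- lapply(seq_len(n_comparisons_b), effects_for_b)
  names(planted_de_b) <- names(lowox_b)

  truth <- list(
    planted_de = list(a = planted_de_a, b = planted_de_b),
    planted_bins = data.frame(
      bin = c(conserved_paths, "26.1", "27.1"),
      class = c(rep("conserved_up", n_conserved_bins), "a_only", "b_only"),
      stringsAsFactors = FALSE),
    ortholog_classes = pairs,
    planted_markers = names(marker_eff),
    decoy_markers = list(abiotic_up = names(decoy_abiotic_eff),
                         below_fold = names(decoy_fold_eff)),
    quorum_a = quorum_a, quorum_b = quorum_b,
    marker_comparisons = marker_comparisons,
    seed = seed)

  list(species_a = species_a, species_b = species_b,
       lowox_a = lowox_a, lowox_b = lowox_b,
       abiotic_a = abiotic_a, abiotic_b = abiotic_b,
       bins_a = bins_a, bins_b = bins_b,
       ortho_sim = ortho_sim, ortho_inp = ortho_inp,
       truth = truth)
}

#' Write a truth object as JSON
#' @param truth truth list from a generator
#' @param path output path
#' @return invisibly, the truth object
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(truth)
}
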