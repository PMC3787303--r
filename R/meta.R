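#' Bundle the comparisons of one species/condition family
#'
#' A `StudySet` collects the per-comparison outputs (ORA tables and contrast
#' results with calls) that the cross-study consensus rules consume, e.g.
#' "the four rice low-oxygen comparisons" or "the Arabidopsis abiotic stress
#' contrasts".
#'
#' @param label set label.
#' @param members list of members, each a list with elements `study_id`,
#'   `contrast` (unique within the set), optional `ora` (OraResult) and
#'   optional `de` (ContrastResult with calls).
#' @return list of class `StudySet`
#' @export
study_set <- function(label, members) {
  cn <- vapply(members, function(m) m$contrast, "")
  if (anyDuplicated(cn))
    stop("duplicate contrast name(s) in study set '", label, "': ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  structure(list(label = label, members = members), class = "StudySet")
}

# bins significantly OVER-represented (z past the positive threshold) in
# the given direction's gene set; under-representation never counts as a
# hit for the consensus rules
sig_bins <- function(ora, direction) {
  unique(ora$bin[ora$direction == direction & ora$significant & ora$z > 0])
}

# contrasts (by name) in which a bin is over-represented in a direction
sig_intervals <- function(ora, bin, direction) {
  unique(ora$contrast[ora$bin == bin & ora$direction == direction &
                        ora$significant & ora$z > 0])
}

#' Functional categories conserved across studies
#'
#' Returns the bins significantly over-represented in the stated direction
#' in every one of the supplied ORA tables (one table per study; a table may
#' span several step-wise contrasts, any of which counts). For step-wise
#' studies each bin carries the interval(s) — contrast names — where it was
#' significant per study, and a `timing_match` flag recording whether the
#' two studies named in `timing_pair` share at least one interval (the
#' "responsive at the same time" annotation of paired aerobic/anaerobic
#' time courses).
#'
#' @param ora_tables named list of >= 2 OraResult tables, one per study.
#' @param direction `"up"` or `"down"`.
#' @param timing_pair optional character vector of two names from
#'   `ora_tables` whose intervals are compared for the timing flag.
#' @return data.frame with columns `bin`, `direction`, one
#'   `intervals.<study>` column per table (comma-joined contrast names) and,
#'   when `timing_pair` is given, `timing_match`.
#' @export
conserved_categories <- function(ora_tables, direction = c("up", "down"),
                                 timing_pair = NULL) {
  direction <- match.arg(direction)
  if (length(ora_tables) < 2L) stop("need >= 2 ORA tables")
  if (is.null(names(ora_tables)))
    names(ora_tables) <- paste0("study", seq_along(ora_tables))
  sets <- lapply(ora_tables, sig_bins, direction = direction)
  shared <- Reduce(intersect, sets)
  out <- data.frame(bin = shared, direction = rep(direction, length(shared)),
                    stringsAsFactors = FALSE)
  for (nm in names(ora_tables)) {
    out[[paste0("intervals.", nm)]] <- vapply(shared, function(b)
      paste(sig_intervals(ora_tables[[nm]], b, direction), collapse = ","),
      "")
  }
  if (!is.null(timing_pair)) {
    stopifnot(length(timing_pair) == 2L,
              all(timing_pair %in% names(ora_tables)))
    out$timing_match <- vapply(shared, function(b) {
      i1 <- sig_intervals(ora_tables[[timing_pair[1]]], b, direction)
      i2 <- sig_intervals(ora_tables[[timing_pair[2]]], b, direction)
      length(intersect(i1, i2)) > 0L
    }, TRUE)
  }
  rownames(out) <- NULL
  out
}

#' Condition-specific functional categories
#'
#' Bins significant (same direction throughout) in the target comparison AND
#' in the co-required comparison AND in none of the excluded comparisons —
#' the rule isolating e.g. categories over-represented versus an aerobic
#' control and over an anaerobic time course while never appearing over the
#' aerobic time course.
#'
#' @param target_ora,corequired_ora OraResult tables.
#' @param excluded_ora list of OraResult tables (may be empty).
#' @param direction `"up"` or `"down"`.
#' @return character vector of bin paths.
#' @export
condition_specific_categories <- function(target_ora, corequired_ora,
                                          excluded_ora = list(),
                                          direction = c("up", "down")) {
  direction <- match.arg(direction)
  hits <- intersect(sig_bins(target_ora, direction),
                    sig_bins(corequired_ora, direction))
  for (ex in excluded_ora)
    hits <- setdiff(hits, sig_bins(ex, direction))
  sort(hits)
}

#' Species-consensus classification of functional categories
#'
#' Per bin and direction, counts in how many comparisons of each species the
#' bin is significantly over-represented, then classifies: `a_only` when the
#' count reaches the species-a quorum `k_a` with zero hits in species b
#' (symmetric for `b_only`), `both` when at least one comparison hits in
#' each species, `neither` otherwise.
#'
#' @param set_a,set_b StudySet with `ora` members (e.g. the four rice and
#'   five Arabidopsis low-oxygen comparisons).
#' @param k_a,k_b species-specific quorums (e.g. 3 of 4 and 4 of 5).
#' @param direction `"up"` or `"down"`.
#' @return data.frame with columns `bin`, `direction`, `count_a`, `count_b`,
#'   `class`.
#' @export
species_consensus <- function(set_a, set_b, k_a, k_b,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (k_a > length(set_a$members) || k_b > length(set_b$members))
    stop("quorum exceeds the number of comparisons in a study set")
  count_hits <- function(set) {
    hits <- lapply(set$members, function(m) sig_bins(m$ora, direction))
    tab <- table(unlist(hits))
    stats::setNames(as.integer(tab), names(tab))
  }
  ca <- count_hits(set_a); cb <- count_hits(set_b)
  bins <- sort(unique(c(names(ca), names(cb))))
  count_a <- ifelse(bins %in% names(ca), ca[bins], 0L)
  count_b <- ifelse(bins %in% names(cb), cb[bins], 0L)
  data.frame(bin = bins, direction = rep(direction, length(bins)),
             count_a = as.integer(count_a), count_b = as.integer(count_b),
             class = classify_consensus(count_a, count_b, k_a, k_b),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify species-consensus hit counts
#'
#' The pure classification rule behind [species_consensus()], exposed so the
#' quorum logic can be checked exhaustively over all count combinations.
#'
#' @param count_a,count_b per-bin significant-comparison counts (vectors).
#' @param k_a,k_b quorums.
#' @return character vector in {"a_only", "b_only", "both", "neither"}.
#' @export
classify_consensus <- function(count_a, count_b, k_a, k_b) {
  ifelse(count_a >= k_a & count_b == 0L, "a_only",
    ifelse(count_b >= k_b & count_a == 0L, "b_only",
      ifelse(count_a >= 1L & count_b >= 1L, "both", "neither")))
}

#' Overlap counts between low-oxygen and abiotic-stress DE sets
#'
#' Entry (i, j) counts the genes differentially expressed in low-oxygen
#' comparison i that are also differentially expressed in abiotic-stress
#' contrast j. In `any_direction` mode a gene overlaps regardless of the
#' direction of its two calls; in `matched` mode the calls must agree
#' (up/up or down/down). Contrast orientation (e.g. a published comparison
#' run as anoxia-vs-air rather than air-vs-anoxia) is applied upstream in
#' the contrast spec, so fold-change signs are already comparable here.
#'
#' @param lowox,abiotic StudySet with `de` members carrying calls.
#' @param mode `"any_direction"` (default) or `"matched"`.
#' @return integer matrix, low-oxygen contrasts x abiotic contrasts.
#' @export
overlap_counts <- function(lowox, abiotic,
                           mode = c("any_direction", "matched")) {
  mode <- match.arg(mode)
  ln <- vapply(lowox$members, function(m) m$contrast, "")
  an <- vapply(abiotic$members, function(m) m$contrast, "")
  out <- matrix(0L, length(ln), length(an), dimnames = list(ln, an))
  for (i in seq_along(ln)) for (j in seq_along(an)) {
    di <- lowox$members[[i]]$de; dj <- abiotic$members[[j]]$de
    if (mode == "any_direction") {
      gi <- di$gene[di$call %in% c("up", "down")]
      gj <- dj$gene[dj$call %in% c("up", "down")]
      out[i, j] <- length(intersect(gi, gj))
    } else {
      out[i, j] <-
        length(intersect(de_genes(di, "up"), de_genes(dj, "up"))) +
        length(intersect(de_genes(di, "down"), de_genes(dj, "down")))
    }
  }
  out
}

#' Identify low-oxygen marker genes
#'
#' A marker is a gene called up with a linear fold-change strictly above
#' `fold_min` in at least `k_min` of the low-oxygen comparisons; with
#' `exclude_abiotic_up` on, any gene called up in any abiotic-stress
#' contrast is removed (a marker must be specific to low oxygen, not a
#' general stress responder). The conventional rule is >50-fold in 2 of 4
#' comparisons (rice, with abiotic exclusion) or 3 of 5 (Arabidopsis).
#'
#' @param lowox StudySet with `de` members carrying calls.
#' @param fold_min linear fold-change threshold (default 50).
#' @param k_min minimum number of passing comparisons (default 2).
#' @param abiotic optional StudySet of abiotic-stress contrasts.
#' @param exclude_abiotic_up apply the abiotic exclusion (default TRUE when
#'   `abiotic` is supplied).
#' @return data.frame with columns `gene`, `n_passing`, `max_fold` (linear,
#'   maximum across passing comparisons), `abiotic_up`, sorted by
#'   `n_passing` then `max_fold`, both descending.
#' @export
find_marker_genes <- function(lowox, fold_min = 50, k_min = 2,
                              abiotic = NULL,
                              exclude_abiotic_up = !is.null(abiotic)) {
  lfc_min <- log2(fold_min)
  pass <- list()
  for (m in lowox$members) {
    d <- m$de
    if (is.null(d$call)) stop("member '", m$contrast, "' carries no calls")
    hit <- d$call == "up" & d$log2fc > lfc_min
    pass[[m$contrast]] <- data.frame(gene = d$gene[hit],
                                     fold = 2^d$log2fc[hit],
                                     stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, pass)
  if (is.null(tab) || nrow(tab) == 0L)
    return(data.frame(gene = character(), n_passing = integer(),
                      max_fold = numeric(), abiotic_up = logical(),
                      stringsAsFactors = FALSE))
  n_passing <- table(tab$gene)
  max_fold <- tapply(tab$fold, tab$gene, max)
  genes <- names(n_passing)[as.integer(n_passing) >= k_min]

  abiotic_up_genes <- character()
  if (!is.null(abiotic))
    abiotic_up_genes <- unique(unlist(lapply(abiotic$members, function(m)
      de_genes(m$de, "up"))))
  out <- data.frame(gene = genes,
                    n_passing = as.integer(n_passing[genes]),
                    max_fold = as.numeric(max_fold[genes]),
                    abiotic_up = genes %in% abiotic_up_genes,
                    stringsAsFactors = FALSE)
  if (exclude_abiotic_up) out <- out[!out$abiotic_up, , drop = FALSE]
  out <- out[order(-out$n_passing, -out$max_fold), , drop = FALSE]
  rownames(out) <- NULL
  out
}
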