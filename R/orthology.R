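#' Cross-species ortholog map from the union of two evidence sources
#'
#' Ortholog pairs are accepted when either a sequence-similarity resource or
#' an Inparanoid-style method (or both) reports them; provenance records
#' which. The relation is many-to-many and direction-agnostic.
#'
#' @param source_sim data.frame of similarity-based pairs with columns
#'   `gene_a`, `gene_b`, optional `pct_identity`.
#' @param source_inp data.frame of Inparanoid-style pairs, same columns.
#' @param species_a,species_b species labels for the a- and b-side ids.
#' @return object of class `OrthologMap` with `species_a`, `species_b` and
#'   `pairs` (data.frame `gene_a`, `gene_b`, `provenance` in
#'   {"similarity", "inparanoid", "both"}, `pct_identity`).
#' @export
union_orthologs <- function(source_sim, source_inp,
                            species_a = "species_a",
                            species_b = "species_b") {
  norm <- function(tab) {
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b") %in% names(tab)))
      stop("ortholog source needs columns gene_a, gene_b")
    if (!"pct_identity" %in% names(tab))
      tab[["pct_identity"]] <- rep(NA_real_, nrow(tab))
    unique(data.frame(gene_a = as.character(tab$gene_a),
                      gene_b = as.character(tab$gene_b),
                      pct_identity = as.numeric(tab$pct_identity),
                      stringsAsFactors = FALSE))
  }
  sim <- norm(source_sim); inp <- norm(source_inp)
  key <- function(tab) paste(tab$gene_a, tab$gene_b, sep = "\r")
  all_pairs <- rbind(sim, inp)
  all_pairs <- all_pairs[!duplicated(key(all_pairs)), , drop = FALSE]
  in_sim <- key(all_pairs) %in% key(sim)
  in_inp <- key(all_pairs) %in% key(inp)
  all_pairs$provenance <- ifelse(in_sim & in_inp, "both",
                                 ifelse(in_sim, "similarity", "inparanoid"))
  # keep any similarity percentage recorded in either source
  pct <- sim$pct_identity[match(key(all_pairs), key(sim))]
  all_pairs$pct_identity <- ifelse(is.na(all_pairs$pct_identity), pct,
                                   all_pairs$pct_identity)
  rownames(all_pairs) <- NULL
  structure(list(species_a = species_a, species_b = species_b,
                 pairs = all_pairs[, c("gene_a", "gene_b", "provenance",
                                       "pct_identity")]),
            class = "OrthologMap")
}

#' @export
print.OrthologMap <- function(x, ...) {
  cat(sprintf("OrthologMap %s <-> %s: %d pairs (%d similarity-only, %d inparanoid-only, %d both)\n",
              x$species_a, x$species_b, nrow(x$pairs),
              sum(x$pairs$provenance == "similarity"),
              sum(x$pairs$provenance == "inparanoid"),
              sum(x$pairs$provenance == "both")))
  invisible(x)
}

#' Map genes to their ortholog sets
#'
#' One-to-many relations are preserved in full; a gene with no recorded
#' ortholog maps to an empty set.
#'
#' @param genes character vector of gene ids.
#' @param map OrthologMap.
#' @param from `"a"` if `genes` are a-side ids (mapped to b-side orthologs),
#'   `"b"` for the reverse direction.
#' @return named list: gene -> character vector of orthologs.
#' @export
map_genes <- function(genes, map, from = c("a", "b")) {
  from <- match.arg(from)
  src <- if (from == "a") map$pairs$gene_a else map$pairs$gene_b
  dst <- if (from == "a") map$pairs$gene_b else map$pairs$gene_a
  out <- lapply(as.character(genes), function(g) unique(dst[src == g]))
  names(out) <- as.character(genes)
  out
}

#' Project contrast results across species through the ortholog map
#'
#' For each source gene, every ortholog contributes one row carrying that
#' ortholog's log2 fold-change and call in each foreign contrast. Orthologs
#' absent from a foreign result (e.g. filtered out by detection calls) are
#' reported as `not_detected` — distinct from a measured but non-significant
#' `ns`.
#'
#' @param genes character vector of source-species gene ids.
#' @param map OrthologMap.
#' @param foreign_results named list of ContrastResult indexed by the
#'   partner species' gene ids; names label the contrast columns.
#' @param from which side of the map `genes` belong to (`"a"` or `"b"`).
#' @return data.frame with columns `gene`, `ortholog`, then
#'   `<contrast>.log2fc` and `<contrast>.call` per foreign contrast.
#' @export
project_contrasts <- function(genes, map, foreign_results,
                              from = c("a", "b")) {
  from <- match.arg(from)
  if (is.null(names(foreign_results)) || any(names(foreign_results) == ""))
    stop("foreign_results must be a named list of contrast results")
  orth <- map_genes(genes, map, from = from)
  src <- rep(names(orth), lengths(orth))
  dst <- unlist(orth, use.names = FALSE)
  out <- data.frame(gene = src %||% character(),
                    ortholog = dst %||% character(),
                    stringsAsFactors = FALSE)
  for (cn in names(foreign_results)) {
    res <- foreign_results[[cn]]
    idx <- match(out$ortholog, res$gene)
    out[[paste0(cn, ".log2fc")]] <- res$log2fc[idx]
    cl <- res$call[idx]
    cl[is.na(cl)] <- "not_detected"
    out[[paste0(cn, ".call")]] <- cl
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read an ortholog pair table TSV
#'
#' Columns `gene_a`, `gene_b`, optional `source` and `pct_identity`.
#' @param path TSV path
#' @return data.frame of pairs
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (!all(c("gene_a", "gene_b") %in% names(tab)))
    stop("ortholog table needs columns gene_a, gene_b: ", path)
  if ("pct_identity" %in% names(tab))
    tab$pct_identity <- as.numeric(tab$pct_identity)
  tab
}

#' Write an ortholog map (provenance column mandatory) as TSV
#' @param map OrthologMap
#' @param path output path
#' @return invisibly, the map
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(map)
}
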