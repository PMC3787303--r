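#' Hierarchical functional-category (bin) annotation
#'
#' Functional categories are organised as a MapMan-style tree of dotted-path
#' bins (`"10"`, `"10.2"`, `"10.2.1"`, ...). A gene assigned to a bin is
#' implicitly a member of every ancestor bin, so enrichment can be evaluated
#' at every level of the hierarchy. Construction materializes this ancestor
#' closure once.
#'
#' @param assignments data.frame with columns `bin_path`, `bin_name`,
#'   `gene_id`; duplicate (gene, bin) rows are deduplicated and implied
#'   ancestor bins are created (named after their path when no name is
#'   supplied anywhere).
#' @return object of class `BinAnnotation` with `bins` (data.frame `path`,
#'   `name`, `parent`), `members` (named list: bin path -> character vector
#'   of member genes, ancestor closure applied) and `direct` (the
#'   deduplicated direct assignments).
#' @export
bin_annotation <- function(assignments) {
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  if (nrow(assignments) == 0L) {
    return(structure(list(
      bins = data.frame(path = character(), name = character(),
                        parent = character(), stringsAsFactors = FALSE),
      members = list(),
      direct = data.frame(gene_id = character(), bin_path = character(),
                          stringsAsFactors = FALSE)),
      class = "BinAnnotation"))
  }
  req <- c("bin_path", "bin_name", "gene_id")
  if (!all(req %in% names(assignments)))
    stop("assignments must have columns bin_path, bin_name, gene_id")
  paths <- as.character(assignments$bin_path)
  bad <- grepl("(^\\.)|(\\.$)|(\\.\\.)", paths) | paths == ""
  if (any(bad))
    stop("malformed bin path (empty segment): '", paths[which(bad)[1]], "'")

  direct <- unique(data.frame(gene_id = as.character(assignments$gene_id),
                              bin_path = paths, stringsAsFactors = FALSE))

  ancestors_of <- function(p) {
    segs <- strsplit(p, ".", fixed = TRUE)[[1]]
    vapply(seq_along(segs), function(k) paste(segs[1:k], collapse = "."), "")
  }
  all_paths <- sort(unique(unlist(lapply(unique(paths), ancestors_of))))
  name_map <- tapply(as.character(assignments$bin_name), paths,
                     function(x) x[1])
  names_out <- ifelse(all_paths %in% names(name_map),
                      unname(name_map[all_paths]), all_paths)
  parent <- vapply(all_paths, function(p) {
    a <- ancestors_of(p)
    if (length(a) > 1L) a[length(a) - 1L] else NA_character_
  }, "")

  # closure: gene in bin b iff some direct path equals b or descends from b
  closure <- lapply(all_paths, function(b) {
    hit <- direct$bin_path == b |
      startsWith(direct$bin_path, paste0(b, "."))
    sort(unique(direct$gene_id[hit]))
  })
  names(closure) <- all_paths

  structure(list(
    bins = data.frame(path = all_paths, name = names_out, parent = parent,
                      stringsAsFactors = FALSE, row.names = NULL),
    members = closure, direct = direct),
    class = "BinAnnotation")
}

#' @export
print.BinAnnotation <- function(x, ...) {
  cat(sprintf("BinAnnotation: %d bins, %d genes, %d direct assignments\n",
              nrow(x$bins), length(unique(x$direct$gene_id)),
              nrow(x$direct)))
  invisible(x)
}

#' Member genes of a bin (ancestor closure applied)
#' @param annot BinAnnotation
#' @param path bin path
#' @return character vector of gene ids (empty if the bin is unknown)
#' @export
bin_members <- function(annot, path) {
  m <- annot$members[[path]]
  if (is.null(m)) character() else m
}

#' Read a MapMan-style bin annotation TSV
#'
#' Columns `bin_path`, `bin_name`, `gene_id`. An empty file yields an
#' annotation with zero bins.
#' @param path TSV file path
#' @return BinAnnotation
#' @export
read_bin_annotation <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  bin_annotation(tab)
}

#' Write a bin annotation's direct assignments as TSV
#' @param annot BinAnnotation
#' @param path output path
#' @return invisibly, the annotation
#' @export
write_bin_annotation <- function(annot, path) {
  nm <- annot$bins$name[match(annot$direct$bin_path, annot$bins$path)]
  tab <- data.frame(bin_path = annot$direct$bin_path, bin_name = nm,
                    gene_id = annot$direct$gene_id,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(annot)
}
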