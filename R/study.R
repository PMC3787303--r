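#' Construct an ExpressionStudy
#'
#' An `ExpressionStudy` bundles a replicated, normalized (log2-scale)
#' gene-by-sample expression matrix with its sample design: which condition
#' (or timepoint within a condition series) and replicate each array belongs
#' to. This is the container every downstream stage (detection filtering,
#' regularized differential expression, time-course contrasts) consumes.
#'
#' @param study_id single character label identifying the study.
#' @param values numeric matrix of log2 normalized intensities, genes in
#'   rows, samples in columns; `dimnames` supply gene and sample ids unless
#'   `gene_ids`/`sample_ids` are given explicitly.
#' @param design data.frame with columns `sample`, `condition`, optional
#'   `timepoint` (integer rank within a condition series, `NA` allowed) and
#'   `replicate`; one row per sample.
#' @param gene_ids,sample_ids optional explicit id vectors overriding
#'   `dimnames(values)`.
#' @param linear_input if `TRUE`, `values` are linear-scale intensities and
#'   are floored at 1 then log2-transformed on construction.
#' @return object of class `ExpressionStudy` with elements `study_id`,
#'   `genes`, `samples`, `values`, `design`.
#' @export
expression_study <- function(study_id, values, design,
                             gene_ids = NULL, sample_ids = NULL,
                             linear_input = FALSE) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(gene_ids) && nrow(values) == 0L) gene_ids <- character()
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample ids are required (dimnames or explicit arguments)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  }
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("matrix dimensions do not match id vectors")
  if (linear_input) values <- log2(pmax(values, 1))
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values")
  dimnames(values) <- list(gene_ids, sample_ids)

  design <- as.data.frame(design, stringsAsFactors = FALSE)
  req <- c("sample", "condition", "replicate")
  if (!all(req %in% names(design)))
    stop("design must have columns sample, condition, replicate")
  if (!"timepoint" %in% names(design)) design$timepoint <- NA_integer_
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  if (anyDuplicated(design$sample))
    stop("design lists sample(s) more than once: ",
         paste(unique(design$sample[duplicated(design$sample)]), collapse = ", "))
  missing_d <- setdiff(sample_ids, design$sample)
  if (length(missing_d))
    stop("sample(s) in matrix missing from design: ",
         paste(missing_d, collapse = ", "))
  missing_m <- setdiff(design$sample, sample_ids)
  if (length(missing_m))
    stop("sample(s) in design missing from matrix: ",
         paste(missing_m, collapse = ", "))
  design <- design[match(sample_ids, design$sample),
                   c("sample", "condition", "timepoint", "replicate")]
  rownames(design) <- NULL
  design$timepoint <- suppressWarnings(as.integer(design$timepoint))

  structure(list(study_id = study_id, genes = gene_ids,
                 samples = sample_ids, values = values, design = design),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy '%s': %d genes x %d samples, %d condition(s)\n",
              x$study_id, length(x$genes), length(x$samples),
              length(unique(x$design$condition))))
  invisible(x)
}

#' Samples belonging to a condition (optionally a timepoint)
#' @param study ExpressionStudy
#' @param condition condition label
#' @param timepoint optional timepoint rank
#' @return character vector of sample ids
#' @export
condition_samples <- function(study, condition, timepoint = NULL) {
  d <- study$design
  keep <- d$condition == condition
  if (!is.null(timepoint)) keep <- keep & !is.na(d$timepoint) & d$timepoint == timepoint
  d$sample[keep]
}

#' Restrict a study to a gene subset (order preserved from the study)
#' @param study ExpressionStudy
#' @param genes character vector of gene ids to keep
#' @return ExpressionStudy
#' @export
subset_genes <- function(study, genes) {
  keep <- study$genes %in% genes
  expression_study(study$study_id, study$values[keep, , drop = FALSE],
                   study$design)
}

# ---- presence calls --------------------------------------------------------

#' Construct MAS5-style presence calls
#'
#' Detection verdicts (`P`resent / `M`arginal / `A`bsent) with per-cell
#' detection p-values, aligned cell-for-cell with an expression matrix. A
#' cell is called present exactly when its detection p-value is below
#' `alpha`; marginal and absent cells both count as not-present when
#' filtering.
#'
#' @param detection_p numeric matrix of detection p-values (genes x samples,
#'   dimnames required).
#' @param alpha detection significance level (default 0.05).
#' @param marginal_alpha upper bound for the marginal band (default 0.065);
#'   cells with `alpha <= p < marginal_alpha` are called `M`.
#' @return object of class `PresenceCalls` with `genes`, `samples`, `call`
#'   (character matrix of "P"/"M"/"A") and `detection_p`.
#' @export
presence_calls <- function(detection_p, alpha = 0.05, marginal_alpha = 0.065) {
  detection_p <- as.matrix(detection_p)
  if (is.null(rownames(detection_p)) || is.null(colnames(detection_p)))
    stop("detection_p needs gene and sample dimnames")
  if (any(detection_p < 0 | detection_p > 1))
    stop("detection p-values must lie in [0, 1]")
  call <- matrix("A", nrow(detection_p), ncol(detection_p),
                 dimnames = dimnames(detection_p))
  call[detection_p < marginal_alpha] <- "M"
  call[detection_p < alpha] <- "P"
  structure(list(genes = rownames(detection_p),
                 samples = colnames(detection_p),
                 call = call, detection_p = detection_p, alpha = alpha),
            class = "PresenceCalls")
}

check_calls_aligned <- function(study, calls) {
  if (!identical(study$genes, calls$genes) ||
      !identical(study$samples, calls$samples))
    stop("presence calls are not aligned with the study ",
         "(gene/sample ids or order differ)")
  invisible(TRUE)
}

#' Filter a study by detection calls
#'
#' Keeps the genes whose detection verdicts satisfy a presence policy and
#' drops the rest, mirroring the standard pre-analysis step of discarding
#' probesets never reliably detected on the array. Marginal calls are
#' treated as not-present (conservative).
#'
#' @param study ExpressionStudy.
#' @param calls PresenceCalls aligned to `study`.
#' @param policy one of `"all_reps_of_any_condition"` (default: present in
#'   every replicate of at least one condition), `"any_sample"`,
#'   `"all_samples"`.
#' @return ExpressionStudy restricted to the passing genes; sample set and
#'   gene order unchanged.
#' @export
apply_presence_filter <- function(study, calls,
                                  policy = c("all_reps_of_any_condition",
                                             "any_sample", "all_samples")) {
  policy <- match.arg(policy)
  check_calls_aligned(study, calls)
  present <- calls$call == "P"
  keep <- switch(policy,
    any_sample = rowSums(present) > 0L,
    all_samples = rowSums(present) == ncol(present),
    all_reps_of_any_condition = {
      conds <- unique(study$design$condition)
      ok <- rep(FALSE, nrow(present))
      for (cc in conds) {
        s <- study$design$sample[study$design$condition == cc]
        ok <- ok | rowSums(present[, s, drop = FALSE]) == length(s)
      }
      ok
    })
  expression_study(study$study_id, study$values[keep, , drop = FALSE],
                   study$design)
}

# ---- TSV IO ----------------------------------------------------------------

#' Read an expression study from matrix + design TSVs
#'
#' The matrix TSV has a header row of sample ids (first header cell is
#' ignored) and gene ids in the first column; the design TSV has columns
#' `sample`, `condition`, optional `timepoint`, `replicate`. Tab-separated,
#' UTF-8, "." decimal, no quoting.
#'
#' @param matrix_path,design_path file paths.
#' @param study_id study label; defaults to the matrix file name sans
#'   extension.
#' @param linear_input declare linear-scale input (log2-transformed with a
#'   floor of 1 on read).
#' @return ExpressionStudy
#' @export
read_expression_study <- function(matrix_path, design_path,
                                  study_id = NULL, linear_input = FALSE) {
  if (is.null(study_id))
    study_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character")
  gene_ids <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = list(gene_ids, colnames(m))))
  bad <- which(is.na(num) & !is.na(m) & m != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                 gene_ids[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, 1], bad[1, 2]]))
  design <- utils::read.delim(design_path, check.names = FALSE)
  expression_study(study_id, num, design, linear_input = linear_input)
}

#' Write an expression study to matrix + design TSVs
#' @param study ExpressionStudy
#' @param matrix_path,design_path output file paths
#' @return invisibly, the study
#' @export
write_expression_study <- function(study, matrix_path, design_path) {
  tab <- data.frame(gene_id = study$genes, study$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(study)
}

#' Read presence calls from a combined call:p TSV
#'
#' Accepts either a single TSV whose cells are `"P:0.003"`-style
#' `call:detection_p` pairs, or (via `p_path`) two parallel TSVs, one of
#' P/M/A codes and one of detection p-values.
#'
#' @param path TSV of combined cells, or of call codes when `p_path` given.
#' @param p_path optional parallel TSV of detection p-values.
#' @param alpha detection alpha used to (re)derive present verdicts.
#' @return PresenceCalls
#' @export
read_presence_calls <- function(path, p_path = NULL, alpha = 0.05) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  gene_ids <- tab[[1L]]
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  if (is.null(p_path)) {
    pv <- matrix(as.numeric(sub("^[PMA]:", "", cells)),
                 nrow(cells), ncol(cells),
                 dimnames = list(gene_ids, colnames(cells)))
  } else {
    ptab <- utils::read.delim(p_path, check.names = FALSE)
    pv <- as.matrix(ptab[, -1L, drop = FALSE])
    dimnames(pv) <- list(as.character(ptab[[1L]]), colnames(pv))
    pv <- pv[gene_ids, colnames(cells), drop = FALSE]
  }
  if (any(is.na(pv))) stop("unparseable detection p-value cell in ", path)
  presence_calls(pv, alpha = alpha)
}

#' Write presence calls as a combined call:p TSV
#' @param calls PresenceCalls
#' @param path output path
#' @return invisibly, the calls
#' @export
write_presence_calls <- function(calls, path) {
  cells <- matrix(sprintf("%s:%.6g", calls$call, calls$detection_p),
                  nrow(calls$call), ncol(calls$call))
  tab <- data.frame(gene_id = calls$genes, cells,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[-1L] <- calls$samples
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}
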