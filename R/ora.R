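#' Two-sided Fisher's exact test for a bin's 2x2 table
#'
#' Tests whether `k` of the `n` differentially expressed genes falling in a
#' bin that holds `K` of the `N` background genes deviates from the
#' hypergeometric expectation, via the 2x2 table
#' `[[k, n-k], [K-k, N-K-n+k]]`. The two-sided probability sums the
#' hypergeometric probabilities of every table (with the same margins) that
#' is no more probable than the observed one.
#'
#' @param k DE genes in the bin; `K` background genes in the bin; `n` DE set
#'   size; `N` background size.
#' @return two-sided probability in (0, 1]
#' @export
fisher_bin_test <- function(k, K, n, N) {
  if (K > N) stop("impossible table: K > N (bin larger than background)")
  if (n > N) stop("impossible table: n > N (DE set larger than background)")
  if (k > min(K, n)) stop("impossible table: k > min(K, n)")
  if (k < max(0, n + K - N))
    stop("impossible table: k < max(0, n + K - N)")
  support <- max(0, n + K - N):min(K, n)
  d <- stats::dhyper(support, K, N - K, n)
  obs <- stats::dhyper(k, K, N - K, n)
  # relative tolerance guards ties broken only by floating-point noise
  min(sum(d[d <= obs * (1 + 1e-7)]), 1)
}

#' Convert a two-sided probability to a signed z-score
#'
#' Maps a two-sided p to the standard-normal quantile
#' \eqn{z = \Phi^{-1}(1 - p/2)}, signed positive for over-representation and
#' negative for under-representation, so that p = 0.05 corresponds to
#' |z| = 1.96 and p = 1 to z = 0.
#'
#' @param p two-sided probability in (0, 1]
#' @param over logical; `TRUE` for over-representation (k/n > K/N)
#' @return signed z-score
#' @export
p_to_signed_z <- function(p, over) {
  if (any(p <= 0)) stop("p must be positive")
  z <- stats::qnorm(1 - p / 2)
  ifelse(over, z, -z)
}

#' PageMan-style over-representation analysis
#'
#' For one contrast's up- and down-regulated gene sets separately, every bin
#' of the hierarchy with at least one background member is tested by
#' Fisher's exact test against the background, and the two-sided probability
#' is converted to a signed z-score (positive when the bin is
#' over-represented in the DE set, negative when under-represented). A bin's
#' membership includes all genes assigned to any of its descendants, so
#' enrichment is evaluated at every level. Significance is `|z| >
#' z_threshold` (default 1.96, i.e. p < 0.05); an optional Bonferroni
#' correction across the tested bins can be switched on.
#'
#' @param de_calls ContrastResult with calls (see [call_de()]).
#' @param bins BinAnnotation.
#' @param background character vector of background gene ids; must contain
#'   the up and down sets. Typically all genes surviving the presence
#'   filter in the study.
#' @param z_threshold significance threshold on |z| (default 1.96).
#' @param bonferroni divide the 0.05-equivalent alpha by the number of
#'   tested bins before converting to the z threshold (default FALSE).
#' @param contrast_name label for the output rows; defaults to the name in
#'   the result's contrast attribute.
#' @return data.frame of class `OraResult` with columns `contrast`,
#'   `direction`, `bin`, `bin_name`, `k`, `K`, `n`, `N`, `p`, `z`,
#'   `significant`.
#' @export
run_ora <- function(de_calls, bins, background, z_threshold = 1.96,
                    bonferroni = FALSE, contrast_name = NULL) {
  if (is.null(contrast_name)) {
    spec <- attr(de_calls, "contrast")
    contrast_name <- if (!is.null(spec)) spec$name else "contrast"
  }
  if (nrow(bins$bins) == 0L) stop("bin annotation is empty")
  background <- unique(as.character(background))
  up <- intersect(de_genes(de_calls, "up"), background)
  down <- intersect(de_genes(de_calls, "down"), background)
  extra <- setdiff(c(de_genes(de_calls, "up"), de_genes(de_calls, "down")),
                   background)
  if (length(extra))
    stop("DE gene(s) missing from background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  if (length(up) == 0L && length(down) == 0L)
    warning("empty DE set for contrast '", contrast_name,
            "'; all z-scores are 0")

  N <- length(background)
  paths <- bins$bins$path
  bg_members <- lapply(paths, function(b)
    intersect(bin_members(bins, b), background))
  keep <- lengths(bg_members) > 0L
  paths <- paths[keep]; bg_members <- bg_members[keep]
  Ks <- lengths(bg_members)
  nm <- bins$bins$name[match(paths, bins$bins$path)]

  one_direction <- function(set, direction) {
    n <- length(set)
    k <- vapply(bg_members, function(m) length(intersect(m, set)), 0L)
    if (n == 0L) {
      p <- rep(1, length(paths)); z <- rep(0, length(paths))
    } else {
      p <- mapply(fisher_bin_test, k, Ks, MoreArgs = list(n = n, N = N))
      over <- k / n > Ks / N
      z <- ifelse(k / n == Ks / N, 0, p_to_signed_z(p, over))
    }
    data.frame(contrast = contrast_name, direction = direction,
               bin = paths, bin_name = nm, k = k, K = Ks, n = n, N = N,
               p = p, z = z, stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- rbind(one_direction(up, "up"), one_direction(down, "down"))
  thr <- if (bonferroni)
    stats::qnorm(1 - (0.05 / length(paths)) / 2) else z_threshold
  out$significant <- abs(out$z) > thr
  class(out) <- c("OraResult", "data.frame")
  out
}

#' Write an ORA result as TSV
#' @param ora OraResult
#' @param path output path
#' @return invisibly, the result
#' @export
write_ora_result <- function(ora, path) {
  utils::write.table(as.data.frame(ora), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ora)
}

#' Read an ORA result TSV
#' @param path TSV path
#' @return OraResult
#' @export
read_ora_result <- function(path) {
  out <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("bin", "direction", "z", "significant") %in% names(out)))
    stop("not an ORA result table: ", path)
  out$bin <- as.character(out$bin)
  out$significant <- as.logical(out$significant)
  class(out) <- c("OraResult", "data.frame")
  out
}
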