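#' Cyber-T tuning parameters
#'
#' The regularized t-test shrinks each gene's within-group variance toward a
#' background variance estimated from genes of similar mean expression.
#' `window_size` sets how many rank-neighbours contribute to that background
#' and `v0` (the prior degrees of freedom) sets how strongly the background
#' is weighted relative to the observed replicate variance.
#'
#' @param window_size odd positive integer, number of genes in the sliding
#'   background window (default 101, the classic web-interface default).
#' @param v0 non-negative prior degrees of freedom (default 10). `v0 = 0`
#'   disables shrinkage and recovers the classical Welch-style statistic.
#' @param min_variance small positive floor applied to observed per-gene
#'   variances before regularization, guarding zero-variance genes.
#' @param df_mode `"regularized"` uses df = n_a + n_b - 2 + 2*v0;
#'   `"classical"` uses n_a + n_b - 2.
#' @return list of class `CyberTParams`
#' @export
cybert_params <- function(window_size = 101L, v0 = 10,
                          min_variance = 1e-8,
                          df_mode = c("regularized", "classical")) {
  window_size <- as.integer(window_size)
  if (window_size < 1L || window_size %% 2L == 0L)
    stop("window_size must be an odd positive integer")
  if (v0 < 0) stop("v0 must be non-negative")
  if (min_variance <= 0) stop("min_variance must be positive")
  structure(list(window_size = window_size, v0 = v0,
                 min_variance = min_variance,
                 df_mode = match.arg(df_mode)),
            class = "CyberTParams")
}

#' Windowed background standard deviation
#'
#' Genes are ranked by mean expression; each gene's background sd is the
#' root-mean-square of the observed sds of the `window_size` genes centered
#' on it in that ranking, the window truncated (shrunk) at the edges. This
#' is the local variance prior of the regularized t-test: genes expressed at
#' similar levels share similar measurement variance, so pooling across the
#' window stabilizes per-gene estimates from few replicates.
#'
#' @param gene_means per-gene group means (used only for ranking).
#' @param gene_sds per-gene observed group sds, aligned with `gene_means`.
#' @param window_size odd positive window width; clipped to the number of
#'   genes (kept odd) when larger.
#' @return numeric vector of background sds aligned with the input.
#' @export
background_sd <- function(gene_means, gene_sds, window_size = 101L) {
  g <- length(gene_means)
  if (g < 2L) stop("need at least 2 genes to estimate a background sd")
  if (length(gene_sds) != g) stop("gene_means and gene_sds must align")
  window_size <- as.integer(window_size)
  if (window_size %% 2L == 0L || window_size < 1L)
    stop("window_size must be odd and positive")
  if (window_size > g) window_size <- if (g %% 2L == 1L) g else g - 1L
  h <- (window_size - 1L) %/% 2L
  ord <- order(gene_means)
  v <- gene_sds[ord]^2
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(g) - h, 1L)
  hi <- pmin(seq_len(g) + h, g)
  bg <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  out <- numeric(g)
  out[ord] <- bg
  out
}

#' Specify a two-group contrast
#'
#' @param study_id study label the groups come from.
#' @param name contrast label (e.g. `"anoxia v control"`, `"3h v 0h"`).
#' @param group_a reference samples; `group_b` treatment samples. Disjoint,
#'   each of size >= 2.
#' @param orientation `+1` or `-1`; `-1` flips the sign of reported log2
#'   fold-changes (used when a published comparison was run in the opposite
#'   direction and must be re-oriented to show the response of interest).
#' @return list of class `ContrastSpec`
#' @export
contrast_spec <- function(study_id, name, group_a, group_b,
                          orientation = 1) {
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)))
    stop("contrast groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each contrast group needs >= 2 samples")
  if (!orientation %in% c(-1, 1)) stop("orientation must be +1 or -1")
  structure(list(study_id = study_id, name = name, group_a = group_a,
                 group_b = group_b, orientation = orientation),
            class = "ContrastSpec")
}

#' Step-wise time-course contrasts
#'
#' For a germination-style time course, builds the contrast of each
#' timepoint against the immediately preceding one: k timepoints yield k-1
#' specs named `"<t_i> v <t_i-1>"`, the earlier timepoint always the
#' reference.
#'
#' @param study ExpressionStudy whose design carries timepoint ranks.
#' @param condition condition label of the series.
#' @return list of `ContrastSpec` (empty for a single timepoint).
#' @export
stepwise_contrasts <- function(study, condition) {
  d <- study$design[study$design$condition == condition, ]
  tps <- sort(unique(d$timepoint[!is.na(d$timepoint)]))
  if (length(tps) < 2L) return(list())
  out <- vector("list", length(tps) - 1L)
  for (i in seq_along(out)) {
    a <- d$sample[!is.na(d$timepoint) & d$timepoint == tps[i]]
    b <- d$sample[!is.na(d$timepoint) & d$timepoint == tps[i + 1L]]
    if (length(a) < 2L || length(b) < 2L)
      stop(sprintf("timepoint %s of condition '%s' has < 2 replicates",
                   tps[if (length(a) < 2L) i else i + 1L], condition))
    out[[i]] <- contrast_spec(study$study_id,
                              sprintf("%s v %s", tps[i + 1L], tps[i]),
                              group_a = a, group_b = b)
  }
  out
}

#' Bayesian-regularized two-group t-test (Cyber-T style)
#'
#' For each gene, the within-group variance is replaced by the regularized
#' estimate
#' \deqn{\tilde\sigma^2 = (v_0 \sigma_0^2 + (n-1) s^2) / (v_0 + n - 1),}
#' a convex combination of the windowed background variance
#' \eqn{\sigma_0^2} (see [background_sd()]) and the observed replicate
#' variance \eqn{s^2}, weighted by the prior degrees of freedom `v0` and the
#' data degrees of freedom. The statistic is
#' \eqn{t = (m_b - m_a)/\sqrt{\tilde\sigma_a^2/n_a + \tilde\sigma_b^2/n_b}}
#' with a two-sided p-value from Student's t on
#' `n_a + n_b - 2 + 2*v0` degrees of freedom (the prior contributes `v0`
#' pseudo-replicates to each group). With `v0 = 0` the statistic reduces
#' exactly to the classical Welch-style t on the observed sds.
#'
#' @param study ExpressionStudy.
#' @param spec ContrastSpec whose groups are samples of `study`.
#' @param params CyberTParams.
#' @return data.frame of class `ContrastResult` with columns `gene`,
#'   `log2fc` (orientation applied), `t`, `p`; `ppde` and `call` columns are
#'   added by [fit_bum_ppde()]/[call_de()]. Attribute `contrast` carries the
#'   spec.
#' @export
cybert_contrast <- function(study, spec, params = cybert_params()) {
  miss <- setdiff(c(spec$group_a, spec$group_b), study$samples)
  if (length(miss))
    stop("contrast sample(s) not in study: ", paste(miss, collapse = ", "))
  xa <- study$values[, spec$group_a, drop = FALSE]
  xb <- study$values[, spec$group_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- pmax(apply(xa, 1L, stats::var), params$min_variance)
  vb <- pmax(apply(xb, 1L, stats::var), params$min_variance)
  v0 <- params$v0
  if (v0 > 0) {
    s0a <- background_sd(ma, sqrt(va), params$window_size)
    s0b <- background_sd(mb, sqrt(vb), params$window_size)
    ra <- (v0 * s0a^2 + (na - 1) * va) / (v0 + na - 1)
    rb <- (v0 * s0b^2 + (nb - 1) * vb) / (v0 + nb - 1)
  } else {
    ra <- va; rb <- vb
  }
  se <- sqrt(ra / na + rb / nb)
  tstat <- (mb - ma) / se
  df <- if (params$df_mode == "regularized") na + nb - 2 + 2 * v0
        else na + nb - 2
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  res <- data.frame(gene = study$genes,
                    log2fc = (mb - ma) * spec$orientation,
                    t = tstat, p = pmin(p, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "contrast") <- spec
  attr(res, "df") <- df
  class(res) <- c("ContrastResult", "data.frame")
  res
}
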