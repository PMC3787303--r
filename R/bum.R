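#' Fit a beta-uniform mixture to p-values and compute PPDE
#'
#' The observed p-value distribution is modelled as
#' \deqn{f(p) = \lambda + (1-\lambda)\, a\, p^{a-1}, \quad 0 < a \le 1,}
#' a uniform null component of weight \eqn{\lambda} plus a beta(a, 1)
#' alternative spiking near zero. The posterior probability of differential
#' expression for a gene with p-value p is the posterior weight of the
#' alternative component,
#' \deqn{\mathrm{PPDE}(p) = (1-\lambda)\, a\, p^{a-1} / f(p).}
#' Fitting is by EM from a fixed grid of 10 starting points, keeping the
#' highest-likelihood solution; in the E-step each p-value's responsibility
#' under the beta component is computed, in the M-step \eqn{\lambda} is the
#' mean null responsibility and \eqn{a} solves the weighted beta score
#' equation in closed form.
#'
#' @param p_values numeric vector of p-values (>= 50 recommended for a
#'   stable fit); values are clipped to `[1e-12, 1]`.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return list with `fit` (class `BumFit`: `lambda`, `a`, `loglik`,
#'   `n_iter`) and `ppde` (per-input posterior probabilities, aligned).
#' @export
fit_bum_ppde <- function(p_values, max_iter = 500L, tol = 1e-8) {
  p <- pmin(pmax(as.numeric(p_values), 1e-12), 1)
  if (length(p) < 2L) stop("need at least 2 p-values to fit the mixture")
  lp <- log(p)

  loglik <- function(lambda, a)
    sum(log(lambda + (1 - lambda) * a * p^(a - 1)))

  run_em <- function(lambda, a) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      fb <- a * p^(a - 1)
      f <- lambda + (1 - lambda) * fb
      r <- (1 - lambda) * fb / f          # responsibility of the beta part
      lambda <- min(max(1 - mean(r), 1e-6), 1 - 1e-6)
      sr <- sum(r)
      a <- if (sr > 0) min(max(-sr / sum(r * lp), 1e-6), 1) else 1
      ll <- loglik(lambda, a)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(lambda = lambda, a = a, loglik = ll, n_iter = it)
  }

  starts <- expand.grid(lambda = c(0.3, 0.5, 0.7, 0.9, 0.99),
                        a = c(0.1, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    cand <- run_em(starts$lambda[i], starts$a[i])
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  if (!is.finite(best$loglik))
    stop("beta-uniform mixture fit did not converge; last iterate lambda=",
         best$lambda, " a=", best$a,
         " -- check the p-value distribution for mass outside (0, 1]")

  fb <- best$a * p^(best$a - 1)
  ppde <- (1 - best$lambda) * fb / (best$lambda + (1 - best$lambda) * fb)
  fit <- structure(list(lambda = best$lambda, a = best$a,
                        loglik = best$loglik, n_iter = best$n_iter),
                   class = "BumFit")
  list(fit = fit, ppde = ppde)
}

#' @export
print.BumFit <- function(x, ...) {
  cat(sprintf("BumFit: lambda = %.4f, a = %.4f, loglik = %.2f (%d EM iterations)\n",
              x$lambda, x$a, x$loglik, x$n_iter))
  invisible(x)
}

#' Add PPDE values to a contrast result
#' @param result ContrastResult from [cybert_contrast()]
#' @return the result with a `ppde` column and a `bum_fit` attribute
#' @export
add_ppde <- function(result) {
  fit <- fit_bum_ppde(result$p)
  result$ppde <- fit$ppde
  attr(result, "bum_fit") <- fit$fit
  result
}

#' Three-part differential-expression call
#'
#' A gene is called `up` when all three rules hold: linear fold-change
#' strictly greater than `fold_threshold` (i.e. `log2fc > log2(fold)`),
#' `p < p_threshold`, and `ppde > ppde_threshold`; symmetric for `down`;
#' otherwise `ns`. Defaults are the conventional 2-fold / p < 0.05 /
#' PPDE > 0.96 triplet.
#'
#' @param result ContrastResult with a populated `ppde` column.
#' @param fold_threshold linear fold-change threshold (default 2).
#' @param p_threshold p-value threshold (default 0.05).
#' @param ppde_threshold PPDE threshold (default 0.96).
#' @return the result with a `call` column (`"up"`, `"down"`, `"ns"`).
#' @export
call_de <- function(result, fold_threshold = 2, p_threshold = 0.05,
                    ppde_threshold = 0.96) {
  if (is.null(result$ppde))
    stop("ppde column missing; run add_ppde() first")
  lfc_min <- log2(fold_threshold)
  sig <- result$p < p_threshold & result$ppde > ppde_threshold
  call <- rep("ns", nrow(result))
  call[sig & result$log2fc > lfc_min] <- "up"
  call[sig & result$log2fc < -lfc_min] <- "down"
  result$call <- call
  result
}

#' Genes called in a direction
#' @param result ContrastResult with calls
#' @param direction `"up"` or `"down"`
#' @return character vector of gene ids
#' @export
de_genes <- function(result, direction = c("up", "down")) {
  direction <- match.arg(direction)
  result$gene[result$call == direction]
}

#' Run the full per-contrast differential-expression stage
#'
#' Convenience wrapper: regularized t-test, beta-uniform-mixture PPDE
#' (fitted per contrast), and the three-part call.
#'
#' @inheritParams cybert_contrast
#' @inheritParams call_de
#' @return ContrastResult with `ppde` and `call` columns
#' @export
run_contrast <- function(study, spec, params = cybert_params(),
                         fold_threshold = 2, p_threshold = 0.05,
                         ppde_threshold = 0.96) {
  res <- cybert_contrast(study, spec, params)
  res <- add_ppde(res)
  call_de(res, fold_threshold, p_threshold, ppde_threshold)
}

#' Write a contrast result as TSV
#' @param result ContrastResult
#' @param path output path
#' @return invisibly, the result
#' @export
write_contrast_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(result)
}

#' Read a contrast result TSV (gene, log2fc, t, p, ppde, call)
#' @param path TSV path
#' @param contrast_name optional contrast label to attach
#' @return ContrastResult
#' @export
read_contrast_result <- function(path, contrast_name = NULL) {
  res <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "log2fc", "p") %in% names(res)))
    stop("not a contrast result table: ", path)
  res$gene <- as.character(res$gene)
  if (!is.null(contrast_name))
    attr(res, "contrast") <- list(study_id = NA_character_,
                                  name = contrast_name)
  class(res) <- c("ContrastResult", "data.frame")
  res
}
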