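# small deterministic fixtures shared across test files

toy_study <- function() {
  values <- matrix(c(7.0, 7.2, 9.1, 8.9,
                     5.0, 5.1, 5.2, 4.9,
                     8.0, 8.3, 8.1, 8.2),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("A_r1", "A_r2", "B_r1", "B_r2")))
  design <- data.frame(sample = colnames(values),
                       condition = c("A", "A", "B", "B"),
                       replicate = c(1, 2, 1, 2))
  expression_study("toy", values, design)
}

# minimal ContrastResult-shaped table for set-logic operations
fake_de <- function(genes, up = character(), down = character(),
                    log2fc = NULL, contrast = "c") {
  call <- ifelse(genes %in% up, "up", ifelse(genes %in% down, "down", "ns"))
  if (is.null(log2fc))
    log2fc <- ifelse(call == "up", 2, ifelse(call == "down", -2, 0))
  res <- data.frame(gene = genes, log2fc = log2fc, t = 0, p = 1, ppde = 0,
                    call = call, stringsAsFactors = FALSE)
  attr(res, "contrast") <- list(study_id = "fake", name = contrast)
  class(res) <- c("ContrastResult", "data.frame")
  res
}

# minimal OraResult-shaped table: one up and one down row per bin, with the
# chosen bins flagged significantly over-represented
fake_ora <- function(bins, sig_up = character(), sig_down = character(),
                     contrast = "c") {
  mk <- function(direction, sig) {
    data.frame(contrast = contrast, direction = direction, bin = bins,
               bin_name = bins, k = 0L, K = 1L, n = 10L, N = 100L,
               p = ifelse(bins %in% sig, 0.001, 0.5),
               z = ifelse(bins %in% sig, 3.29, 0.67),
               significant = bins %in% sig, stringsAsFactors = FALSE)
  }
  out <- rbind(mk("up", sig_up), mk("down", sig_down))
  class(out) <- c("OraResult", "data.frame")
  out
}

# random significance pattern over bins for property tests
rand_ora <- function(bins, contrast = "c", p_sig = 0.3) {
  fake_ora(bins,
           sig_up = bins[stats::runif(length(bins)) < p_sig],
           sig_down = bins[stats::runif(length(bins)) < p_sig],
           contrast = contrast)
}
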