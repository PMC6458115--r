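#' Simulate quick-FISH spot-count tables for specimens of known sex
#'
#' Per cell, the expected count (2 for ZZ males, 3 for ZW females) is seen
#' with probability `signal_rate`; otherwise the count is corrupted the
#' way real interphase preparations fail — mostly signal dropout or spot
#' overlap (count lowered by 1-2), occasionally a spurious extra signal.
#'
#' @param sexes Character vector of true sexes (one specimen each).
#' @param cells_range Range of cells scored per specimen.
#' @param signal_rate Probability a cell shows the expected count.
#' @param seed Integer seed.
#' @return Data frame: `specimen`, `true_sex`, `cell_index`, `count`.
#' @export
simulate_spot_counts <- function(sexes, cells_range = c(40L, 90L),
                                 signal_rate = 0.9, seed = 1L) {
  set.seed(seed)
  out <- lapply(seq_along(sexes), function(i) {
    expected <- if (sexes[i] == "female") 3L else 2L
    n <- sample(cells_range[1]:cells_range[2], 1L)
    ok <- runif(n) < signal_rate
    counts <- rep(expected, n)
    n_bad <- sum(!ok)
    if (n_bad) {
      delta <- sample(c(-1L, -2L, 1L), n_bad, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
      counts[!ok] <- pmax(0L, expected + delta)
    }
    data.frame(specimen = sprintf("sp%02d", i), true_sex = sexes[i],
               cell_index = seq_len(n), count = counts,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate qPCR records for a W-linked target
#'
#' The reference (single-copy) channel has the same mean Ct in both sexes;
#' the W-linked target amplifies earlier in females by `delta_cycles`
#' (higher copy number = lower Ct). Replicates get technical noise of SD
#' `replicate_sd`.
#'
#' @param sexes Character vector of true sexes (one specimen each).
#' @param ct_reference_mean Mean reference Ct.
#' @param ct_target_female Mean target Ct in females.
#' @param delta_cycles Cycles by which males trail females on the target.
#' @param replicate_sd Technical replicate SD.
#' @param n_replicates Replicates per channel.
#' @param seed Integer seed.
#' @return List of records suitable for [call_sex_qpcr()], each with
#'   `specimen`, `sex_label`, `ct_target`, `ct_reference`.
#' @export
simulate_qpcr_records <- function(sexes, ct_reference_mean = 21,
                                  ct_target_female = 18,
                                  delta_cycles = 4, replicate_sd = 0.08,
                                  n_replicates = 2L, seed = 1L) {
  set.seed(seed)
  lapply(seq_along(sexes), function(i) {
    mu_t <- ct_target_female +
      if (sexes[i] == "male") delta_cycles else 0
    list(specimen = sprintf("sp%02d", i), sex_label = sexes[i],
         ct_target = rnorm(n_replicates, mu_t, replicate_sd),
         ct_reference = rnorm(n_replicates, ct_reference_mean, replicate_sd))
  })
}
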