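#' Bundled candidate-family table (published worked example)
#'
#' The per-library abundances (% of library nucleotides), divergences,
#' printed F/M ratios and FISH annotations of the 30 satellite families
#' with the highest female/male abundance ratios in a characiform fish
#' with a ZZ/ZW system. Families absent from the male library carry `NA`
#' male columns; printed abundances are rounded to six decimals, so
#' recomputed F/M ratios agree with the printed ones to about four
#' significant figures. Used as a worked example for [fm_ratio()] and
#' [rank_candidates()].
#'
#' @return Data frame with columns `sf`, `family`, `rul`, `at_content`,
#'   `n_variants`, `abundance_female`, `abundance_male`,
#'   `divergence_female`, `divergence_male`, `fm_ratio_printed`,
#'   `pattern`, `location`.
#' @export
candidate_families <- function() {
  path <- system.file("extdata", "candidate_families.tsv",
                      package = "satellitome", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
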