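#' Packaged validation mixture dataset
#'
#' Loads the packaged accuracy/precision validation dataset: 16 mixture
#' conditions of five purified HTT-exon1 standards (Q25/Q38/Q48/Q55/Q72) —
#' one recipe measured at five total concentrations, three distinct recipes
#' sharing a theoretical average near Q48, and eight recipes spanning
#' theoretical averages 38-58 in 2.5-residue steps — together with the
#' experimentally determined average polyQ length (mean, propagated SD of
#' duplicates) and the reported Cv% and %RE for each condition.
#'
#' @return list with `mixtures` (named list of [mixture_spec()]) and
#'   `results` (data frame: `table`, `label`, `mean_q`, `sd_q`,
#'   `printed_cv_percent`, `printed_re_percent`), aligned by `label`.
#' @export
load_validation_mixtures <- function() {
  rec <- system.file("extdata", "mixture_recipes.csv", package = "polyQavg",
                     mustWork = TRUE)
  res <- system.file("extdata", "validation_results.csv", package = "polyQavg",
                     mustWork = TRUE)
  mixtures <- read_mixture_recipes(rec)
  results <- utils::read.csv(res, stringsAsFactors = FALSE)
  # Table 1 repeats one recipe over concentrations; keep alignment by label
  results <- results[match(names(mixtures), results$label), , drop = FALSE]
  rownames(results) <- NULL
  list(mixtures = mixtures, results = results)
}
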