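#' Define a protein mixture of known polyQ composition
#'
#' A validation mixture combines purified HTT-exon1 proteins of distinct
#' polyQ lengths in stated fractions at a total concentration, emulating the
#' mosaic of repeat lengths produced by somatic CAG instability. Fractions
#' are treated as molar fractions.
#'
#' @param q_lengths integer polyQ lengths, distinct and positive.
#' @param fractions fractions in `[0, 1]` summing to 1 (within 1e-6).
#' @param total_concentration total protein concentration in pM.
#' @param label text label for reports.
#' @return object of class `"mixture_spec"`.
#' @export
mixture_spec <- function(q_lengths, fractions, total_concentration = NA_real_,
                         label = "") {
  q <- as.numeric(q_lengths); f <- as.numeric(fractions)
  if (length(q) != length(f) || length(q) == 0L) {
    stop("`q_lengths` and `fractions` must be non-empty and aligned", call. = FALSE)
  }
  if (any(q <= 0)) stop("polyQ lengths must be positive", call. = FALSE)
  if (anyDuplicated(q)) stop("polyQ lengths must be distinct", call. = FALSE)
  if (any(f < 0 | f > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-6) {
    stop("fractions must sum to 1 (got ", format(sum(f)), ")", call. = FALSE)
  }
  structure(list(q_lengths = q, fractions = f,
                 total_concentration = total_concentration,
                 label = as.character(label)[1]),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("Mixture '%s' (total %g pM): %s\n", x$label, x$total_concentration,
              paste(sprintf("Q%g:%g%%", x$q_lengths, 100 * x$fractions),
                    collapse = " ")))
  invisible(x)
}

#' Theoretical average polyQ length of a mixture
#'
#' Fraction-weighted mean of the component polyQ lengths; always lies within
#' the span of the component lengths.
#'
#' @param mix a [mixture_spec()].
#' @return average polyQ length in glutamine residues.
#' @export
theoretical_average_polyq <- function(mix) {
  if (abs(sum(mix$fractions) - 1) > 1e-6) {
    stop("invalid mixture: fractions do not sum to 1", call. = FALSE)
  }
  sum(mix$fractions * mix$q_lengths)
}

#' Percent relative error
#'
#' `100 * |measured - theoretical| / theoretical`; the standard accuracy
#' metric for quantitative-assay validation.
#'
#' @param measured,theoretical values in the same units; `theoretical > 0`.
#' @return percent relative error (>= 0).
#' @export
percent_relative_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical reference must be > 0", call. = FALSE)
  100 * abs(measured - theoretical) / theoretical
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean`; the standard precision metric.
#'
#' @param mean mean value, > 0.
#' @param sd standard deviation, >= 0.
#' @return Cv in percent.
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (any(mean <= 0)) stop("mean must be > 0", call. = FALSE)
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  100 * sd / mean
}

#' Accuracy/precision report for a set of mixtures
#'
#' Combines the theoretical average of each mixture with its experimentally
#' determined estimate into the standard validation summary: mean, SD,
#' Cv% and %RE per mixture. Rendered values are rounded to 2 decimals.
#'
#' @param mixtures list of [mixture_spec()] objects.
#' @param estimates aligned list of estimates; each a list with `q_mean` and
#'   `q_sd` (e.g. [estimate_average_polyq()] results).
#' @return data frame with columns `label`, `theoretical_q`, `mean_q`, `sd_q`,
#'   `cv_percent`, `re_percent`.
#' @export
accuracy_table <- function(mixtures, estimates) {
  if (length(mixtures) != length(estimates)) {
    stop("`mixtures` and `estimates` must be aligned lists of equal length",
         call. = FALSE)
  }
  if (length(mixtures) == 0L) {
    return(data.frame(label = character(), theoretical_q = numeric(),
                      mean_q = numeric(), sd_q = numeric(),
                      cv_percent = numeric(), re_percent = numeric()))
  }
  rows <- lapply(seq_along(mixtures), function(i) {
    mix <- mixtures[[i]]; est <- estimates[[i]]
    theo <- theoretical_average_polyq(mix)
    data.frame(label = mix$label,
               theoretical_q = round(theo, 2),
               mean_q = round(est$q_mean, 2),
               sd_q = round(est$q_sd, 2),
               cv_percent = round(coefficient_of_variation(est$q_mean, est$q_sd), 2),
               re_percent = round(percent_relative_error(est$q_mean, theo), 2))
  })
  do.call(rbind, rows)
}

#' Read mixture recipes from a delimited text file
#'
#' Expected columns: `label`, `total_concentration_pM`, `q_length`,
#' `fraction` — one row per mixture component. Rows sharing a label form one
#' mixture. The packaged validation recipes (see
#' `system.file("extdata", package = "polyQavg")`) use this format.
#'
#' @param path CSV file path.
#' @return named list of [mixture_spec()] objects, in file order.
#' @export
read_mixture_recipes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "total_concentration_pM", "q_length", "fraction")
  if (!all(need %in% names(df))) {
    stop("recipe file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  labels <- unique(df$label)
  out <- lapply(labels, function(lab) {
    sub <- df[df$label == lab, , drop = FALSE]
    mixture_spec(sub$q_length, sub$fraction,
                 total_concentration = sub$total_concentration_pM[1],
                 label = lab)
  })
  names(out) <- labels
  out
}
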