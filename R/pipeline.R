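#' Detection limit for immunoassay QC
#'
#' Samples whose signal does not exceed `background_mean + k * background_sd`
#' (default `k = 3`) are below the level of detection and excluded from
#' ratio computation.
#'
#' @param background_mean,background_sd background signal statistics
#'   (counts; `background_sd >= 0`).
#' @param k SD multiplier (> 0, default 3).
#' @return object of class `"detection_limit"`.
#' @export
detection_limit <- function(background_mean, background_sd, k = 3) {
  if (background_sd < 0) stop("`background_sd` must be >= 0", call. = FALSE)
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  structure(list(background_mean = background_mean,
                 background_sd = background_sd, k = k,
                 limit = background_mean + k * background_sd),
            class = "detection_limit")
}

#' @export
print.detection_limit <- function(x, ...) {
  cat(sprintf("Detection limit: background %g + %g SD(%g) = %g counts\n",
              x$background_mean, x$k, x$background_sd, x$limit))
  invisible(x)
}

#' Detection-limit QC check
#'
#' Passes iff `signal > background_mean + k * background_sd` (strict: a
#' signal exactly at the limit fails).
#'
#' @param signal signal(s) in counts.
#' @param limit a [detection_limit()].
#' @return logical vector, `TRUE` = detectable.
#' @export
qc_detection_limit <- function(signal, limit) {
  signal > limit$limit
}

#' Normalise an immunoassay signal by a western-blot band quantity
#'
#' Divides the signal by the band quantity and propagates both uncertainties
#' through the ratio rule ([propagate_ratio_sd()]).
#'
#' @param msd_signal,msd_sd signal and its SD.
#' @param wb_amount,wb_sd band quantity (> 0) and its SD.
#' @return list with `value` and `sd`.
#' @export
wb_normalize <- function(msd_signal, msd_sd, wb_amount, wb_sd = 0) {
  if (wb_amount <= 0) stop("`wb_amount` must be > 0", call. = FALSE)
  r <- propagate_ratio_sd(msd_signal, msd_sd, wb_amount, wb_sd)
  list(value = r$ratio, sd = r$sd)
}

#' Batch concentration correction factors from gel band signals
#'
#' Spectrophotometric concentrations of purified standard proteins are
#' adjusted by the relative amount of full-length product on a gel: each
#' batch's factor is its band signal divided by the mean band signal across
#' all batches, so the factors average to exactly 1.
#'
#' @param q_values polyQ lengths of the batches (>= 2).
#' @param band_signals fluorescence band quantities, all > 0.
#' @return data frame with columns `q` and `factor`.
#' @export
concentration_correction_factors <- function(q_values, band_signals) {
  if (length(band_signals) < 2L) stop("need >= 2 batches", call. = FALSE)
  if (length(q_values) != length(band_signals)) {
    stop("misaligned inputs", call. = FALSE)
  }
  if (any(!is.finite(band_signals)) || any(band_signals <= 0)) {
    stop("band signals must be finite and > 0", call. = FALSE)
  }
  data.frame(q = q_values, factor = band_signals / mean(band_signals))
}

#' Regress protein-level signal ratio on DNA-level average CAG length
#'
#' Ordinary least squares of the mHTT/total-HTT signal ratio on the average
#' CAG repeat length, per antibody pair. Samples failing QC (when a
#' detection limit and total-channel signals are supplied) are excluded and
#' reported.
#'
#' @param samples data frame with columns `ratio`, `avg_cag`, optionally
#'   `antibody_pair` (default one pair) and `total_signal` (for QC).
#' @param limit optional [detection_limit()] applied to `total_signal`.
#' @return data frame with one row per antibody pair: `antibody_pair`,
#'   `slope`, `intercept`, `r_squared`, `n`, `n_excluded`.
#' @export
correlate_protein_dna <- function(samples, limit = NULL) {
  df <- as.data.frame(samples)
  if (!all(c("ratio", "avg_cag") %in% names(df))) {
    stop("`samples` needs `ratio` and `avg_cag` columns", call. = FALSE)
  }
  if (is.null(df$antibody_pair)) df$antibody_pair <- "default"
  n_excluded <- 0L
  if (!is.null(limit) && !is.null(df$total_signal)) {
    keep <- qc_detection_limit(df$total_signal, limit)
    n_excluded <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  out <- lapply(split(df, df$antibody_pair), function(sub) {
    if (nrow(sub) < 3L) {
      stop("fewer than 3 usable samples for antibody pair '",
           sub$antibody_pair[1], "'", call. = FALSE)
    }
    fit <- stats::lm(ratio ~ avg_cag, data = sub)
    # collinear (noiseless) input is a legitimate case: R^2 = 1, but
    # summary.lm warns about the perfect fit
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(antibody_pair = sub$antibody_pair[1],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2,
               n = nrow(sub), n_excluded = n_excluded)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a polyQ calibration from standard-curve panels
#'
#' Full calibration chain: fit a weighted 4PL to every standard in both
#' antibody channels, extract each curve's linear-dynamic-range slope,
#' form the per-Q slope ratios (polyQ channel / total channel) with
#' propagated SDs, and select the best regression family of ratio vs Q.
#'
#' Both routes the method admits are supported: `"slope_ratio"` calibrates on
#' ratios of linear-dynamic-range slopes (the standard-curve route), while
#' `"signal_ratio"` calibrates on ratios of background-subtracted replicate
#' mean signals at one matched load inside the linear range (the route used
#' for sample quantification, where all samples are measured at the same
#' amount of total protein). The two coincide in the proportional regime;
#' signal-ratio mode avoids window-selection variability and must be matched
#' to the load at which samples are later measured.
#'
#' @param polyq_series,total_series named lists of [dose_response_series()]
#'   (one per standard, aligned with `q_values`).
#' @param q_values polyQ lengths of the standards.
#' @param weighting passed to [fit_four_pl()].
#' @param mode `"slope_ratio"` or `"signal_ratio"`.
#' @param load concentration (pM) of the matched load; required for
#'   `"signal_ratio"` mode and must be a measured standard concentration.
#' @return list with `model` (a [calibration_model()]) and `table`
#'   (per-Q data frame of slopes/signals, SDs and ratios).
#' @export
build_calibration <- function(polyq_series, total_series, q_values,
                              weighting = "inverse_y_squared",
                              mode = c("slope_ratio", "signal_ratio"),
                              load = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(polyq_series) == length(q_values),
            length(total_series) == length(q_values))
  rows <- lapply(seq_along(q_values), function(i) {
    fp <- fit_four_pl(polyq_series[[i]], weighting)
    ft <- fit_four_pl(total_series[[i]], weighting)
    if (mode == "slope_ratio") {
      sp <- determine_linear_range(polyq_series[[i]], fp)
      st <- determine_linear_range(total_series[[i]], ft)
      r <- slope_ratio(sp, st)
      data.frame(q = q_values[i],
                 slope_polyq = sp$slope, slope_polyq_sd = sp$slope_sd,
                 slope_total = st$slope, slope_total_sd = st$slope_sd,
                 ratio = r$ratio, ratio_sd = r$sd)
    } else {
      if (is.null(load)) stop("`load` is required in signal_ratio mode",
                              call. = FALSE)
      wp <- polyq_series[[i]]$concentration == load
      wt <- total_series[[i]]$concentration == load
      if (!any(wp) || !any(wt)) {
        stop("no wells at the matched load ", load, " pM", call. = FALSE)
      }
      r <- signal_ratio(polyq_series[[i]]$signal[wp],
                        total_series[[i]]$signal[wt],
                        background = c(polyq = fp$params$bottom,
                                       total = ft$params$bottom))
      data.frame(q = q_values[i],
                 net_polyq = mean(polyq_series[[i]]$signal[wp]) - fp$params$bottom,
                 net_total = mean(total_series[[i]]$signal[wt]) - ft$params$bottom,
                 ratio = r$ratio, ratio_sd = r$sd)
    }
  })
  tab <- do.call(rbind, rows)
  model <- select_regression_model(tab$q, tab$ratio)
  list(model = model, table = tab, mode = mode, load = load)
}

#' Ratio of polyQ-channel to total-channel signals for one sample
#'
#' Computes the mHTT/total-HTT signal ratio from replicate well signals
#' measured at one matched protein load, with optional background
#' subtraction, and propagates the replicate uncertainty (SD of the
#' replicate mean in each channel, combined by the ratio rule).
#'
#' @param polyq_signals,total_signals replicate well signals (counts).
#' @param background background to subtract from every well before forming
#'   the ratio: a scalar applied to both channels, or a length-2 vector
#'   `c(polyq = ..., total = ...)` of per-channel fitted `Bottom` values
#'   (default 0 for already-net signals).
#' @return list with `ratio` and `sd`.
#' @export
signal_ratio <- function(polyq_signals, total_signals, background = 0) {
  bg <- rep_len(unname(background), 2L)
  np <- polyq_signals - bg[1]
  nt <- total_signals - bg[2]
  if (any(nt <= 0)) stop("total-channel net signals must be > 0", call. = FALSE)
  mp <- mean(np); mt <- mean(nt)
  sdp <- if (length(np) > 1) stats::sd(np) / sqrt(length(np)) else 0
  sdt <- if (length(nt) > 1) stats::sd(nt) / sqrt(length(nt)) else 0
  propagate_ratio_sd(mp, sdp, mt, sdt)
}

#' End-to-end analysis of a synthetic cohort
#'
#' For every sample of a [simulate_cohort()] output: estimate average polyQ
#' length from the protein ratio through the supplied calibration, compute
#' the DNA-level average CAG from the peak trace, and regress the protein
#' ratio on the DNA average.
#'
#' @param cohort a `"synthetic_cohort"` object.
#' @param model a [calibration_model()] (e.g. from [build_calibration()]).
#' @param threshold_factor peak threshold for the CAG computation.
#' @return list with `per_sample` (data frame: `sample_id`, `true_avg_cag`,
#'   `avg_cag_dna`, `ratio`, `ratio_sd`, `q_mean`, `q_sd`, `cv_percent`,
#'   `re_percent`) and `regression` (from [correlate_protein_dna()]).
#' @export
analyze_cohort <- function(cohort, model, threshold_factor = 0.05) {
  rows <- lapply(cohort, function(s) {
    est <- estimate_average_polyq(s$ratio, s$ratio_sd, model)
    cag <- average_cag(s$dna_trace, two_alleles = FALSE,
                       threshold_factor = threshold_factor)
    data.frame(sample_id = s$sample_id,
               true_avg_cag = s$true_avg_cag,
               avg_cag_dna = cag$combined_average,
               ratio = s$ratio, ratio_sd = s$ratio_sd,
               q_mean = est$q_mean, q_sd = est$q_sd,
               cv_percent = coefficient_of_variation(est$q_mean, est$q_sd),
               re_percent = percent_relative_error(est$q_mean, s$true_avg_cag))
  })
  per_sample <- do.call(rbind, rows)
  reg <- correlate_protein_dna(data.frame(ratio = per_sample$ratio,
                                          avg_cag = per_sample$avg_cag_dna))
  list(per_sample = per_sample, regression = reg)
}

#' Write a fit report for a panel of series
#'
#' One row per series: 4PL parameters and SDs, weighted SSE, linear-range
#' bounds, slope and slope SD — the standard calibration summary table.
#'
#' @param series_list named list of [dose_response_series()].
#' @param path output CSV path.
#' @param weighting passed to [fit_four_pl()].
#' @return the report data frame, invisibly; written to `path`.
#' @export
write_fit_report <- function(series_list, path, weighting = "inverse_y_squared") {
  rows <- lapply(series_list, function(s) {
    fit <- fit_four_pl(s, weighting)
    sl <- tryCatch(determine_linear_range(s, fit), error = function(e) NULL)
    data.frame(sample_id = attr(s, "sample_id"),
               antibody_pair = attr(s, "antibody_pair"),
               bottom = fit$params$bottom, bottom_sd = fit$param_sd[["bottom"]],
               top = fit$params$top, top_sd = fit$param_sd[["top"]],
               ec50 = fit$params$ec50, ec50_sd = fit$param_sd[["ec50"]],
               hillslope = fit$params$hillslope,
               hillslope_sd = fit$param_sd[["hillslope"]],
               weighted_sse = fit$weighted_sse, r_squared = fit$r_squared,
               converged = fit$converged,
               window_lo = if (is.null(sl)) NA_real_ else sl$window_lo,
               window_hi = if (is.null(sl)) NA_real_ else sl$window_hi,
               slope = if (is.null(sl)) NA_real_ else sl$slope,
               slope_sd = if (is.null(sl)) NA_real_ else sl$slope_sd)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  utils::write.csv(report, path, row.names = FALSE)
  invisible(report)
}
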