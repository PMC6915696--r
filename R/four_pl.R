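#' Four-parameter logistic (4PL) dose-response model
#'
#' The 4PL curve describes the sigmoidal response of a sandwich immunoassay
#' (electrochemiluminescence counts vs analyte concentration):
#' \deqn{signal = Bottom + \frac{x^{Hill} (Top - Bottom)}{x^{Hill} + EC50^{Hill}}}
#' where `Bottom` and `Top` are the signal plateaus, `EC50` is the
#' concentration giving a signal halfway between them, and `Hill` sets the
#' steepness of the transition.
#'
#' @param params a [four_pl_params()] object (or anything coercible: a named
#'   list/vector with `bottom`, `top`, `ec50`, `hillslope`).
#' @param x non-negative concentration(s), same units as `ec50` (typically pM).
#' @return numeric vector of predicted signals; `bottom` at `x = 0`
#'   (the limiting value for positive Hill slope).
#' @seealso [fit_four_pl()], [four_pl_params()]
#' @export
evaluate_four_pl <- function(params, x) {
  params <- four_pl_params(params)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`x` must be finite and >= 0", call. = FALSE)
  }
  b <- params$bottom; t <- params$top; e <- params$ec50; h <- params$hillslope
  xh <- x^h
  out <- b + xh * (t - b) / (xh + e^h)
  out[x == 0] <- b
  out
}

#' Construct and validate 4PL parameters
#'
#' @param bottom,top signal plateaus (counts); `top >= bottom`.
#' @param ec50 concentration at half-maximal signal; must be > 0.
#' @param hillslope dimensionless steepness; must be > 0.
#' @return an object of class `"four_pl_params"` (a named list).
#' @export
four_pl_params <- function(bottom, top, ec50, hillslope) {
  if (missing(top) && (is.list(bottom) || (is.numeric(bottom) && !is.null(names(bottom))))) {
    p <- as.list(bottom)
    bottom <- p$bottom; top <- p$top; ec50 <- p$ec50; hillslope <- p$hillslope
  }
  vals <- c(bottom = bottom, top = top, ec50 = ec50, hillslope = hillslope)
  if (length(vals) != 4L || any(!is.finite(vals))) {
    stop("4PL parameters must be four finite numbers (bottom, top, ec50, hillslope)",
         call. = FALSE)
  }
  if (ec50 <= 0) stop("`ec50` must be > 0", call. = FALSE)
  if (hillslope <= 0) stop("`hillslope` must be > 0", call. = FALSE)
  if (top < bottom) stop("`top` must be >= `bottom`", call. = FALSE)
  structure(list(bottom = bottom, top = top, ec50 = ec50, hillslope = hillslope),
            class = "four_pl_params")
}

#' @export
print.four_pl_params <- function(x, ...) {
  cat(sprintf("4PL parameters: Bottom=%.4g  Top=%.4g  EC50=%.4g  HillSlope=%.4g\n",
              x$bottom, x$top, x$ec50, x$hillslope))
  invisible(x)
}

#' Assemble a dose-response series
#'
#' One sample/antibody-pair combination with replicate signal measurements at
#' a ladder of concentrations (pM) or total-protein loads (ug).
#'
#' @param sample_id,antibody_pair character labels.
#' @param concentration numeric, >= 0.
#' @param signal numeric electrochemiluminescence counts, finite.
#' @param replicate integer replicate ids (default all 1).
#' @param units `"pM"` or `"ug"`; one unit per series, never mixed.
#' @return an object of class `"dose_response_series"`: a data frame with
#'   attributes `sample_id`, `antibody_pair`, `units`.
#' @export
dose_response_series <- function(sample_id, antibody_pair, concentration, signal,
                                 replicate = 1L, units = "pM") {
  units <- match.arg(units, c("pM", "ug"))
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(signal))) stop("signals must be finite", call. = FALSE)
  df <- data.frame(concentration = as.numeric(concentration),
                   signal = as.numeric(signal),
                   replicate = as.integer(rep_len(replicate, length(signal))))
  structure(df,
            sample_id = as.character(sample_id)[1],
            antibody_pair = as.character(antibody_pair)[1],
            units = units,
            class = c("dose_response_series", "data.frame"))
}

#' @export
print.dose_response_series <- function(x, ...) {
  cat(sprintf("Dose-response series '%s' (%s): %d points, %d concentrations [%s]\n",
              attr(x, "sample_id"), attr(x, "antibody_pair"),
              nrow(x), length(unique(x$concentration)), attr(x, "units")))
  print(as.data.frame(x), ...)
  invisible(x)
}

four_pl_resid <- function(par, x, y, w) {
  # par on working scale: bottom, log(top - bottom), log(ec50), log(hill)
  b <- par[1]; t <- b + exp(par[2]); e <- exp(par[3]); h <- exp(par[4])
  xh <- x^h
  yhat <- b + xh * (t - b) / (xh + e^h)
  yhat[x == 0] <- b
  sqrt(w) * (y - yhat)
}

fourpl_start_list <- function(x, y) {
  # deterministic data-driven multi-start heuristics
  b0 <- min(y); t0 <- max(y)
  half <- (b0 + t0) / 2
  e0 <- x[which.min(abs(y - half))]
  if (e0 <= 0) e0 <- stats::median(x[x > 0])
  spread <- t0 - b0
  if (spread <= 0) spread <- max(abs(t0), 1)
  starts <- list()
  for (h in c(0.5, 1, 2)) {
    starts[[length(starts) + 1L]] <- c(b0, log(spread), log(e0), log(h))
  }
  # wider EC50 bracketing starts at Hill = 1
  for (mult in c(0.2, 5)) {
    starts[[length(starts) + 1L]] <- c(b0, log(spread), log(e0 * mult), log(1))
  }
  starts
}

#' Fit a four-parameter logistic curve by weighted least squares
#'
#' Minimises \eqn{\sum_i w_i (y_i - \hat y_i)^2} over the four 4PL parameters
#' with Levenberg-Marquardt iterations from a deterministic list of
#' data-driven starting points; with `weighting = "inverse_y_squared"`
#' (the default, standard for immunoassay calibration) \eqn{w_i = 1/y_i^2}
#' using the observed signals. Replicate wells enter as individual points.
#'
#' @param series a [dose_response_series()] with >= 5 distinct concentrations.
#' @param weighting `"inverse_y_squared"` (requires all signals > 0) or `"none"`.
#' @return an object of class `"fourpl_fit"`: list with `params`
#'   ([four_pl_params()]), `param_sd` (per-parameter standard deviations from
#'   the weighted-least-squares covariance), `weighted_sse`, `r_squared`
#'   (weighted), `converged`, `n_points`, `weighting`.
#' @export
fit_four_pl <- function(series, weighting = c("inverse_y_squared", "none")) {
  weighting <- match.arg(weighting)
  x <- series$concentration; y <- series$signal
  if (length(unique(x)) < 5L) {
    stop("4PL fitting requires >= 5 distinct concentrations", call. = FALSE)
  }
  if (weighting == "inverse_y_squared" && any(y <= 0)) {
    stop("1/Y^2 weighting requires all signals > 0; remove non-positive signals",
         call. = FALSE)
  }
  w <- if (weighting == "inverse_y_squared") 1 / y^2 else rep(1, length(y))

  best <- NULL
  for (st in fourpl_start_list(x, y)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = four_pl_resid, x = x, y = y, w = w,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12 * best$sse) {
      best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    stop("4PL optimisation failed from every starting point", call. = FALSE)
  }
  fit <- best$fit
  par <- fit$par
  params <- four_pl_params(bottom = par[1], top = par[1] + exp(par[2]),
                           ec50 = exp(par[3]), hillslope = exp(par[4]))
  converged <- fit$info %in% 1:4

  # SDs on the natural parameter scale via the weighted Gauss-Newton covariance
  theta <- c(params$bottom, params$top, params$ec50, params$hillslope)
  J <- fourpl_jacobian(theta, x)
  Jw <- sqrt(w) * J
  dof <- length(y) - 4L
  s2 <- if (dof > 0) best$sse / dof else NA_real_
  param_sd <- rep(NA_real_, 4)
  JtJ <- crossprod(Jw)
  cv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (!is.null(cv) && is.finite(s2)) {
    vars <- diag(cv) * s2
    vars[vars < 0] <- NA_real_
    param_sd <- sqrt(vars)
  }
  names(param_sd) <- c("bottom", "top", "ec50", "hillslope")

  # weighted R^2 against the weighted mean
  ybar <- sum(w * y) / sum(w)
  sst <- sum(w * (y - ybar)^2)
  r2 <- if (sst > 0) 1 - best$sse / sst else NA_real_

  structure(list(params = params, param_sd = param_sd,
                 weighted_sse = best$sse, r_squared = r2,
                 converged = converged, n_points = length(y),
                 weighting = weighting,
                 sample_id = attr(series, "sample_id"),
                 antibody_pair = attr(series, "antibody_pair"),
                 units = attr(series, "units")),
            class = "fourpl_fit")
}

fourpl_jacobian <- function(theta, x, eps = 1e-6) {
  f <- function(th) {
    p <- four_pl_params(bottom = th[1], top = th[2], ec50 = th[3], hillslope = th[4])
    evaluate_four_pl(p, x)
  }
  J <- matrix(0, length(x), 4)
  for (j in 1:4) {
    h <- eps * max(abs(theta[j]), 1)
    thp <- theta; thp[j] <- thp[j] + h
    thm <- theta; thm[j] <- thm[j] - h
    # keep perturbed parameters in their valid half-spaces
    if (j %in% 3:4) thm[j] <- max(thm[j], theta[j] / 2)
    if (j == 2) thm[j] <- max(thm[j], theta[1])
    J[, j] <- (f(thp) - f(thm)) / (thp[j] - thm[j])
  }
  J
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit for '%s' (%s), %d points, weighting = %s\n",
              x$sample_id, x$antibody_pair, x$n_points, x$weighting))
  print(x$params)
  cat(sprintf("  weighted SSE = %.6g, R^2 = %.6f, converged = %s\n",
              x$weighted_sse, x$r_squared, x$converged))
  invisible(x)
}

#' Linear dynamic range and proportional-response slope
#'
#' In the linear dynamic range the assay obeys `signal = concentration * slope`
#' (after background): the regime used for quantification. The range is found
#' by scanning windows of consecutive standards (sorted by concentration):
#' after subtracting the fitted `Bottom`, a window is accepted when the
#' 1/y^2-weighted through-origin fit has (uncentred) R^2 >= `min_r_squared`
#' and every point back-calculates to within `back_calc_tol` of its nominal
#' concentration. The widest accepted window wins; ties go to the window at
#' lower concentrations.
#'
#' @param series a [dose_response_series()].
#' @param fit a converged [fit_four_pl()] result for the same series.
#' @param min_points minimum number of distinct concentrations in a window.
#' @param min_r_squared acceptance threshold for the through-origin fit.
#' @param back_calc_tol maximum relative deviation of back-calculated from
#'   nominal concentration (0.2 = +-20%).
#' @return an object of class `"slope_estimate"`: `slope`, `slope_sd`,
#'   `window_lo`, `window_hi`, `n_points_used`, `fit_r_squared`.
#' @export
determine_linear_range <- function(series, fit,
                                   min_points = 3L,
                                   min_r_squared = 0.98,
                                   back_calc_tol = 0.2) {
  if (!isTRUE(fit$converged)) {
    stop("linear-range determination requires a converged 4PL fit", call. = FALSE)
  }
  bottom <- fit$params$bottom
  df <- data.frame(x = series$concentration, y = series$signal - bottom,
                   raw = series$signal)
  df <- df[df$x > 0, , drop = FALSE]
  concs <- sort(unique(df$x))
  if (length(concs) < min_points) {
    stop("fewer than ", min_points, " positive concentrations available", call. = FALSE)
  }

  best <- NULL
  fail_reason <- "no window met the linearity criteria"
  # widest windows first; among equal widths, lower concentrations first
  for (width in seq(length(concs), min_points)) {
    for (lo in seq_len(length(concs) - width + 1L)) {
      win <- concs[lo:(lo + width - 1L)]
      sub <- df[df$x %in% win, , drop = FALSE]
      est <- origin_fit(sub$x, sub$y, sub$raw)
      if (!is.finite(est$slope) || est$slope <= 0) {
        fail_reason <- "through-origin slope not positive"
        next
      }
      if (est$r2 < min_r_squared) {
        fail_reason <- sprintf("through-origin R^2 %.4f < %.4f", est$r2, min_r_squared)
        next
      }
      back <- sub$y / est$slope
      relerr <- abs(back - sub$x) / sub$x
      if (any(relerr > back_calc_tol)) {
        fail_reason <- sprintf("back-calculated concentration off by %.1f%% (> %.0f%%)",
                               100 * max(relerr), 100 * back_calc_tol)
        next
      }
      best <- list(est = est, win = win, n = nrow(sub))
      break
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    stop("no linear dynamic range found: ", fail_reason, call. = FALSE)
  }
  structure(list(slope = best$est$slope, slope_sd = best$est$slope_sd,
                 window_lo = min(best$win), window_hi = max(best$win),
                 n_points_used = best$n, fit_r_squared = best$est$r2),
            class = "slope_estimate")
}

origin_fit <- function(x, y, raw_signal) {
  # weighted (1/raw_signal^2) through-origin straight line after background
  # subtraction; uncentred R^2 as is standard for regression through the origin
  w <- 1 / raw_signal^2
  sxx <- sum(w * x^2)
  slope <- sum(w * x * y) / sxx
  res <- y - slope * x
  n <- length(y)
  s2 <- sum(w * res^2) / max(n - 1L, 1L)
  slope_sd <- sqrt(s2 / sxx)
  sst <- sum(w * y^2)
  r2 <- if (sst > 0) 1 - sum(w * res^2) / sst else NA_real_
  list(slope = slope, slope_sd = slope_sd, r2 = r2)
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf(
    "Linear-range slope: %.6g +- %.3g over [%g, %g] (%d points, R^2 = %.5f)\n",
    x$slope, x$slope_sd, x$window_lo, x$window_hi, x$n_points_used,
    x$fit_r_squared))
  invisible(x)
}

#' Ratio of two linear-range slopes with propagated SD
#'
#' The polyQ-antibody slope normalised by the total-antibody slope is the
#' quantity that calibrates against polyQ length. Uncertainty follows the
#' standard relative-error-in-quadrature rule for a ratio
#' (see [propagate_ratio_sd()]).
#'
#' @param numerator,denominator [determine_linear_range()] results (or any
#'   list with `slope` and `slope_sd`).
#' @return list with `ratio` and `sd`.
#' @export
slope_ratio <- function(numerator, denominator) {
  if (!is.finite(denominator$slope) || denominator$slope <= 0) {
    stop("denominator slope must be > 0", call. = FALSE)
  }
  propagate_ratio_sd(numerator$slope, numerator$slope_sd,
                     denominator$slope, denominator$slope_sd)
}
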