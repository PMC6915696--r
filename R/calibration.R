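#' Construct a polyQ-length calibration model
#'
#' Maps polyQ length Q (glutamine residues) to the expected mHTT/total-HTT
#' signal ratio r through one of four two-coefficient families:
#' linear `r = a + b*Q`, exponential `r = a*exp(b*Q)`, logarithmic
#' `r = a + b*ln(Q)`, power `r = a*Q^b`. Each family is strictly monotone in
#' Q (for `b != 0`), so it has a closed-form inverse used for estimation.
#'
#' @param family one of `"linear"`, `"exponential"`, `"logarithmic"`, `"power"`.
#' @param a,b family coefficients; `b` must be nonzero (monotonicity), and
#'   `a > 0` for the exponential and power families.
#' @param r_squared coefficient of determination on the ratio scale.
#' @param q_domain length-2 numeric: Q range of the training data.
#' @param ratio_range length-2 numeric: ratio range of the training data
#'   (estimates outside it are flagged as extrapolated).
#' @return object of class `"calibration_model"`.
#' @export
calibration_model <- function(family, a, b, r_squared = NA_real_,
                              q_domain = c(NA_real_, NA_real_),
                              ratio_range = c(NA_real_, NA_real_)) {
  family <- match.arg(family, c("linear", "exponential", "logarithmic", "power"))
  if (!is.finite(a) || !is.finite(b)) stop("coefficients must be finite", call. = FALSE)
  if (b == 0) stop("`b` must be nonzero for a monotone calibration", call. = FALSE)
  if (family %in% c("exponential", "power") && a <= 0) {
    stop("`a` must be > 0 for the ", family, " family", call. = FALSE)
  }
  if (is.finite(r_squared) && (r_squared > 1 + 1e-12)) {
    stop("`r_squared` must be <= 1", call. = FALSE)
  }
  structure(list(family = family, a = a, b = b, r_squared = r_squared,
                 q_domain = as.numeric(q_domain),
                 ratio_range = as.numeric(ratio_range)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  form <- switch(x$family,
                 linear      = sprintf("r = %.6g + %.6g * Q", x$a, x$b),
                 exponential = sprintf("r = %.6g * exp(%.6g * Q)", x$a, x$b),
                 logarithmic = sprintf("r = %.6g + %.6g * ln(Q)", x$a, x$b),
                 power       = sprintf("r = %.6g * Q^%.6g", x$a, x$b),
                 constant    = sprintf("r = %.6g", x$a))
  cat(sprintf("PolyQ calibration (%s): %s\n", x$family, form))
  cat(sprintf("  R^2 = %.6f, Q domain [%g, %g]\n",
              x$r_squared, x$q_domain[1], x$q_domain[2]))
  invisible(x)
}

#' Evaluate a calibration model at polyQ length(s)
#'
#' @param object a [calibration_model()].
#' @param q polyQ lengths (must be > 0 for the logarithmic/power families).
#' @param ... unused.
#' @return predicted signal ratios.
#' @export
predict.calibration_model <- function(object, q, ...) {
  if (object$family %in% c("logarithmic", "power") && any(q <= 0)) {
    stop("Q must be > 0 for the ", object$family, " family", call. = FALSE)
  }
  switch(object$family,
         linear      = object$a + object$b * q,
         exponential = object$a * exp(object$b * q),
         logarithmic = object$a + object$b * log(q),
         power       = object$a * q^object$b,
         constant    = rep(object$a, length(q)))
}

fit_one_family <- function(family, q, r) {
  tryCatch({
    coefs <- switch(family,
      linear = {
        f <- stats::lm(r ~ q); c(stats::coef(f)[[1]], stats::coef(f)[[2]])
      },
      logarithmic = {
        if (any(q <= 0)) return(NULL)
        f <- stats::lm(r ~ log(q)); c(stats::coef(f)[[1]], stats::coef(f)[[2]])
      },
      exponential = {
        if (any(r <= 0)) return(NULL)
        f0 <- stats::lm(log(r) ~ q)
        st <- list(a = exp(stats::coef(f0)[[1]]), b = stats::coef(f0)[[2]])
        # warnOnly + suppress: on exact data nls cannot improve the start
        # and warns; the fit is judged by R^2 afterwards
        f <- suppressWarnings(
          stats::nls(r ~ a * exp(b * q), start = st,
                     control = stats::nls.control(warnOnly = TRUE, maxiter = 200)))
        unname(stats::coef(f))
      },
      power = {
        if (any(r <= 0) || any(q <= 0)) return(NULL)
        f0 <- stats::lm(log(r) ~ log(q))
        st <- list(a = exp(stats::coef(f0)[[1]]), b = stats::coef(f0)[[2]])
        f <- suppressWarnings(
          stats::nls(r ~ a * q^b, start = st,
                     control = stats::nls.control(warnOnly = TRUE, maxiter = 200)))
        unname(stats::coef(f))
      })
    if (is.null(coefs) || any(!is.finite(coefs)) || coefs[2] == 0) return(NULL)
    m <- calibration_model(family, coefs[1], coefs[2])
    pred <- predict(m, q)
    ss_res <- sum((r - pred)^2)
    ss_tot <- sum((r - mean(r))^2)
    m$r_squared <- 1 - ss_res / ss_tot
    m
  }, error = function(e) NULL)
}

#' Select the best-fitting regression family for ratio vs polyQ length
#'
#' Fits linear, logarithmic, power and exponential models of the signal ratio
#' as a function of polyQ length by least squares on the ratio scale and
#' returns the family with the highest R^2. Ties within `tie_tol` are broken
#' in the order linear > logarithmic > power > exponential (simplest family
#' preferred). Replicate-level data may be supplied as repeated Q values;
#' R^2 is then computed at the level supplied.
#'
#' @param q_values polyQ lengths (>= 3 distinct values).
#' @param responses signal ratios, same length.
#' @param tie_tol R^2 tie tolerance.
#' @return the winning [calibration_model()], with `q_domain` and
#'   `ratio_range` set from the training data.
#' @export
select_regression_model <- function(q_values, responses, tie_tol = 1e-9) {
  q <- as.numeric(q_values); r <- as.numeric(responses)
  if (length(q) != length(r)) stop("inputs must have equal length", call. = FALSE)
  if (length(unique(q)) < 3L) {
    stop("calibration requires >= 3 distinct Q values", call. = FALSE)
  }
  if (stats::var(r) == 0) {
    stop("degenerate data: responses have zero variance", call. = FALSE)
  }
  families <- c("linear", "logarithmic", "power", "exponential")
  fits <- lapply(families, fit_one_family, q = q, r = r)
  names(fits) <- families
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("all candidate families failed to fit", call. = FALSE)
  r2 <- vapply(fits, function(m) m$r_squared, numeric(1))
  best <- fits[[which(r2 >= max(r2) - tie_tol)[1]]]  # list order = preference order
  best$q_domain <- range(q)
  best$ratio_range <- range(r)
  best
}

#' Ratio with propagated standard deviation
#'
#' For a ratio A/B of two measured quantities, the first-order propagated
#' uncertainty combines the relative errors in quadrature:
#' \deqn{SD_{A/B} = \frac{A}{B}\sqrt{(SD_A/A)^2 + (SD_B/B)^2}}
#'
#' @param a,sd_a numerator and its SD (`sd_a >= 0`; `a != 0` when `sd_a > 0`).
#' @param b,sd_b denominator and its SD (`b != 0`).
#' @return list with `ratio` and `sd`.
#' @export
propagate_ratio_sd <- function(a, sd_a, b, sd_b) {
  if (b == 0) stop("denominator must be nonzero", call. = FALSE)
  if (sd_a < 0 || sd_b < 0) stop("SDs must be >= 0", call. = FALSE)
  if (a == 0 && sd_a > 0) {
    stop("relative error undefined: numerator is 0 with nonzero SD", call. = FALSE)
  }
  ratio <- a / b
  rel_a <- if (a == 0) 0 else sd_a / a
  rel_b <- sd_b / b
  list(ratio = ratio, sd = abs(ratio) * sqrt(rel_a^2 + rel_b^2))
}

invert_calibration <- function(model, ratio) {
  a <- model$a; b <- model$b
  switch(model$family,
         linear      = (ratio - a) / b,
         exponential = { if (ratio / a <= 0) stop("ratio outside the exponential family's range",
                                                  call. = FALSE)
                         log(ratio / a) / b },
         logarithmic = exp((ratio - a) / b),
         power       = { if (ratio / a <= 0) stop("ratio outside the power family's range",
                                                  call. = FALSE)
                         (ratio / a)^(1 / b) })
}

#' Estimate average polyQ length from a measured signal ratio
#'
#' Inverts the calibration model analytically and propagates the ratio's
#' uncertainty to the Q scale by the delta method:
#' `q_sd = ratio_sd * |dQ/dr|` at the estimate. With `monte_carlo = TRUE`
#' the SD is instead taken from the inverses of normal ratio draws, useful
#' for strongly nonlinear families at large relative SDs.
#'
#' @param ratio measured mHTT/total-HTT signal ratio.
#' @param ratio_sd its standard deviation (>= 0).
#' @param model a [calibration_model()].
#' @param monte_carlo logical; use Monte-Carlo inversion for the SD.
#' @param n_draws number of draws when `monte_carlo = TRUE`.
#' @return object of class `"polyq_estimate"`: `q_mean`, `q_sd`,
#'   `extrapolated` (TRUE when the ratio lies outside the training range).
#' @export
estimate_average_polyq <- function(ratio, ratio_sd = 0, model,
                                   monte_carlo = FALSE, n_draws = 1e5) {
  if (ratio_sd < 0) stop("`ratio_sd` must be >= 0", call. = FALSE)
  q_mean <- invert_calibration(model, ratio)
  a <- model$a; b <- model$b
  dq_dr <- switch(model$family,
                  linear      = 1 / b,
                  exponential = 1 / (b * ratio),
                  logarithmic = q_mean / b,
                  power       = q_mean / (b * ratio))
  if (monte_carlo && ratio_sd > 0) {
    draws <- stats::rnorm(n_draws, ratio, ratio_sd)
    ok <- switch(model$family,
                 linear = rep(TRUE, n_draws),
                 logarithmic = rep(TRUE, n_draws),
                 draws / a > 0)
    q_sd <- stats::sd(vapply(draws[ok], function(rr) invert_calibration(model, rr),
                             numeric(1)))
  } else {
    q_sd <- ratio_sd * abs(dq_dr)
  }
  rr <- model$ratio_range
  extrapolated <- if (all(is.finite(rr))) (ratio < min(rr) || ratio > max(rr)) else NA
  structure(list(q_mean = q_mean, q_sd = q_sd, extrapolated = extrapolated),
            class = "polyq_estimate")
}

#' @export
print.polyq_estimate <- function(x, ...) {
  cat(sprintf("Average polyQ length: %.2f +- %.2f residues%s\n",
              x$q_mean, x$q_sd,
              if (isTRUE(x$extrapolated)) "  [extrapolated]" else ""))
  invisible(x)
}

#' Predicted signal fold increase relative to a reference polyQ length
#'
#' At a constant amount of protein, the polyQ-antibody signal grows with
#' polyQ length; this predicts `model(Q)/model(q_ref)` over a grid of Q.
#'
#' @param model a [calibration_model()].
#' @param q_ref reference polyQ length (fold = 1 there).
#' @param q_values polyQ lengths to evaluate.
#' @return numeric vector of fold values.
#' @export
predict_fold_increase <- function(model, q_ref, q_values) {
  ref <- predict(model, q_ref)
  if (!is.finite(ref) || ref <= 0) {
    stop("model value at the reference Q must be > 0", call. = FALSE)
  }
  predict(model, q_values) / ref
}

#' Model 4PL parameter trends across polyQ lengths
#'
#' Across a panel of per-Q standard-curve fits, `Bottom` and `HillSlope` are
#' effectively constant while `Top` and `EC50` vary systematically with polyQ
#' length. This pools `Bottom` and `HillSlope` as means and models `Top(Q)`
#' and `EC50(Q)` each with [select_regression_model()], enabling prediction
#' of a full dose-response curve at any Q in the training domain.
#'
#' @param q_values polyQ lengths (>= 3) of the fitted standards.
#' @param fits list of converged [fit_four_pl()] results, aligned with
#'   `q_values`.
#' A parameter whose per-Q values are (numerically) constant — e.g. the
#' total-antibody channel's `Top` — is represented by an internal constant
#' trend rather than a regression family.
#'
#' @return object of class `"param_trend_model"`: `bottom_pooled`,
#'   `hillslope_pooled`, `top_model`, `ec50_model`, `q_domain`,
#'   `nonmonotone_top` warning flag (set when the fitted `Top(Q)` is not
#'   strictly increasing over the domain).
#' @export
fit_param_trends <- function(q_values, fits) {
  if (length(q_values) != length(fits)) stop("misaligned inputs", call. = FALSE)
  if (length(q_values) < 3L) stop("need >= 3 Q values", call. = FALSE)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv)) stop("all per-Q fits must have converged", call. = FALSE)
  bottoms <- vapply(fits, function(f) f$params$bottom, numeric(1))
  tops <- vapply(fits, function(f) f$params$top, numeric(1))
  ec50s <- vapply(fits, function(f) f$params$ec50, numeric(1))
  hills <- vapply(fits, function(f) f$params$hillslope, numeric(1))
  fit_trend <- function(q, v) {
    if (stats::sd(v) <= 1e-10 * max(abs(mean(v)), 1)) {
      return(structure(list(family = "constant", a = mean(v), b = 0,
                            r_squared = 1, q_domain = range(q),
                            ratio_range = rep(mean(v), 2)),
                       class = "calibration_model"))
    }
    select_regression_model(q, v)
  }
  top_model <- fit_trend(q_values, tops)
  ec50_model <- fit_trend(q_values, ec50s)
  grid <- seq(min(q_values), max(q_values), length.out = 101)
  top_pred <- predict(top_model, grid)
  nonmono <- any(diff(top_pred) <= 0)
  structure(list(bottom_pooled = mean(bottoms),
                 hillslope_pooled = mean(hills),
                 top_model = top_model, ec50_model = ec50_model,
                 q_domain = range(q_values),
                 nonmonotone_top = nonmono),
            class = "param_trend_model")
}

#' @export
print.param_trend_model <- function(x, ...) {
  cat(sprintf("4PL parameter trends over Q in [%g, %g]\n",
              x$q_domain[1], x$q_domain[2]))
  cat(sprintf("  pooled Bottom = %.4g, pooled HillSlope = %.4g\n",
              x$bottom_pooled, x$hillslope_pooled))
  cat("  Top(Q): "); print(x$top_model)
  cat("  EC50(Q): "); print(x$ec50_model)
  if (isTRUE(x$nonmonotone_top)) cat("  warning: fitted Top(Q) is not increasing\n")
  invisible(x)
}

#' Predict a full 4PL curve for an arbitrary polyQ length
#'
#' @param trends a [fit_param_trends()] result.
#' @param q polyQ length (within or near the training domain).
#' @return a [four_pl_params()] object.
#' @export
predict_curve_for_q <- function(trends, q) {
  four_pl_params(bottom = trends$bottom_pooled,
                 top = predict(trends$top_model, q),
                 ec50 = predict(trends$ec50_model, q),
                 hillslope = trends$hillslope_pooled)
}

#' Write / read a calibration model as YAML
#'
#' Round-trips the family, coefficients, R^2, Q domain and training ratio
#' range losslessly through a YAML text file.
#'
#' @param model a [calibration_model()].
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a [calibration_model()].
#' @export
write_calibration <- function(model, path) {
  payload <- list(family = model$family,
                  a = model$a, b = model$b,
                  r_squared = model$r_squared,
                  q_domain = model$q_domain,
                  ratio_range = model$ratio_range)
  yaml::write_yaml(payload, path, precision = 17)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- yaml::read_yaml(path)
  calibration_model(p$family, p$a, p$b, r_squared = p$r_squared,
                    q_domain = unlist(p$q_domain),
                    ratio_range = unlist(p$ratio_range))
}
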