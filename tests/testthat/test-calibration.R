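test_that("select_regression_model recovers the generating family exactly", {
  q <- c(19, 32, 38, 48, 55, 72)
  lin <- select_regression_model(q, 0.5 + 0.1 * q)
  expect_equal(lin$family, "linear")
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_equal(c(lin$a, lin$b), c(0.5, 0.1), tolerance = 1e-9)

  pow <- select_regression_model(q, 2 * q^1.5)
  expect_equal(pow$family, "power")
  expect_equal(pow$r_squared, 1, tolerance = 1e-9)
  expect_equal(c(pow$a, pow$b), c(2, 1.5), tolerance = 1e-6)

  expl <- select_regression_model(q, 0.2 * exp(0.04 * q))
  expect_equal(expl$family, "exponential")
  expect_equal(c(expl$a, expl$b), c(0.2, 0.04), tolerance = 1e-6)

  logm <- select_regression_model(q, -1 + 2 * log(q))
  expect_equal(logm$family, "logarithmic")

  expect_error(select_regression_model(q, rep(3, 6)), "degenerate")
  expect_error(select_regression_model(c(19, 19, 19), c(1, 2, 3)), "3 distinct")
})

test_that("reported R^2 equals the closed-form 1 - SSres/SStot", {
  q <- c(19, 25, 32, 38, 44, 48, 55, 72)
  set.seed(101)
  r <- 0.5 + 0.1 * q + rnorm(8, 0, 0.1)
  m <- select_regression_model(q, r)
  pred <- predict(m, q)
  r2_direct <- 1 - sum((r - pred)^2) / sum((r - mean(r))^2)
  expect_equal(m$r_squared, r2_direct, tolerance = 1e-12)
  # the winner is never beaten by a candidate beyond the tie tolerance
  for (fam in c("linear", "logarithmic")) {
    alt <- stats::lm(if (fam == "linear") r ~ q else r ~ log(q))
    expect_gte(m$r_squared + 1e-9, summary(alt)$r.squared)
  }
  # with low noise the generating family is recovered
  set.seed(102)
  r2 <- 0.5 + 0.1 * q + rnorm(8, 0, 0.005)
  expect_equal(select_regression_model(q, r2)$family, "linear")
})

test_that("estimate_average_polyq inverts every family in closed form", {
  q <- c(19, 25, 32, 38, 44, 48, 55, 72)
  fams <- list(
    select_regression_model(q, 0.5 + 0.1 * q),
    select_regression_model(q, 0.2 * exp(0.04 * q)),
    select_regression_model(q, -1 + 2 * log(q)),
    select_regression_model(q, 2 * q^1.5)
  )
  for (m in fams) {
    # round trip at every training point
    for (qq in q) {
      est <- estimate_average_polyq(predict(m, qq), 0, m)
      expect_equal(est$q_mean, qq, tolerance = 1e-9)
      expect_equal(est$q_sd, 0)
      expect_false(est$extrapolated)
    }
  }
  # explicit linear inverse
  mlin <- fams[[1]]
  est <- estimate_average_polyq(5.3, 0, mlin)
  expect_equal(est$q_mean, 48, tolerance = 1e-12)
  # extrapolation is flagged, never clipped
  big <- estimate_average_polyq(predict(mlin, 140), 0, mlin)
  expect_equal(big$q_mean, 140, tolerance = 1e-9)
  expect_true(big$extrapolated)
  # non-invertible input for families requiring positive ratios
  mexp <- fams[[2]]
  expect_error(estimate_average_polyq(-0.5, 0, mexp), "range")
})

test_that("delta-method q_sd matches Monte-Carlo inversion within 2%", {
  q <- c(19, 25, 32, 38, 44, 48, 55, 72)
  m <- select_regression_model(q, 0.5 + 0.1 * q)
  ratio <- 5.3; ratio_sd <- 0.25
  est <- estimate_average_polyq(ratio, ratio_sd, m)
  set.seed(202)
  draws <- (rnorm(1e6, ratio, ratio_sd) - m$a) / m$b
  expect_equal(est$q_sd, sd(draws), tolerance = 0.02)
  # the built-in Monte-Carlo mode agrees too
  set.seed(203)
  est_mc <- estimate_average_polyq(ratio, ratio_sd, m, monte_carlo = TRUE,
                                   n_draws = 2e5)
  expect_equal(est_mc$q_sd, est$q_sd, tolerance = 0.02)
  # power family: delta method within 3 SE of Monte-Carlo at 5% relative SD
  mp <- select_regression_model(q, 2 * q^1.5)
  rp <- predict(mp, 48)
  estp <- estimate_average_polyq(rp, 0.05 * rp, mp)
  set.seed(204)
  drp <- rnorm(1e6, rp, 0.05 * rp)
  qdr <- (drp[drp > 0] / mp$a)^(1 / mp$b)
  se_mc <- sd(qdr) / sqrt(2 * (length(qdr) - 1))  # SE of an SD estimate
  expect_lt(abs(estp$q_sd - sd(qdr)), 3 * se_mc + 0.03 * sd(qdr))
})

test_that("propagate_ratio_sd implements the quadrature rule and its symmetries", {
  r0 <- propagate_ratio_sd(100, 0, 50, 0)
  expect_equal(r0$ratio, 2); expect_equal(r0$sd, 0)
  r1 <- propagate_ratio_sd(100, 10, 50, 5)
  expect_equal(r1$ratio, 2)
  expect_equal(r1$sd, 2 * sqrt(0.02), tolerance = 1e-12)
  # swapping numerator and denominator preserves the relative SD
  r2 <- propagate_ratio_sd(50, 5, 100, 10)
  expect_equal(r2$ratio, 0.5)
  expect_equal(r2$sd / r2$ratio, r1$sd / r1$ratio, tolerance = 1e-12)
  # Monte-Carlo cross-check at 10% relative SDs
  set.seed(301)
  draws <- rnorm(1e6, 100, 10) / rnorm(1e6, 50, 5)
  expect_equal(r1$sd, sd(draws), tolerance = 0.03)
  expect_error(propagate_ratio_sd(0, 1, 50, 5), "undefined")
  expect_error(propagate_ratio_sd(10, 1, 0, 5), "nonzero")
})

test_that("predict_fold_increase normalises at the reference and inherits monotonicity", {
  q <- c(19, 25, 32, 38, 44, 48, 55, 72)
  m <- select_regression_model(q, 0.5 + 0.1 * q)
  expect_equal(predict_fold_increase(m, 38, 38), 1)
  folds <- predict_fold_increase(m, 38, seq(38, 62, by = 1))
  expect_true(all(diff(folds) > 0))
  # brute-force scan oracle: smallest dQ with fold >= 2 at 0.1-residue steps
  grid <- seq(38, 100, by = 0.1)
  fg <- predict(m, grid) / predict(m, 38)
  dq_brute <- grid[which(fg >= 2)[1]] - 38
  dq_pkg <- {
    f <- predict_fold_increase(m, 38, grid)
    grid[which(f >= 2)[1]] - 38
  }
  expect_equal(dq_pkg, dq_brute)
})

test_that("parameter trends pool constants and model Top/EC50 vs Q", {
  qs <- c(25, 38, 48, 55, 72)
  fits <- lapply(qs, function(q) {
    fit_stub(four_pl_params(100, 50 * q, 2000 - 10 * q, 1))
  })
  tr <- fit_param_trends(qs, fits)
  expect_equal(tr$bottom_pooled, 100)
  expect_equal(tr$hillslope_pooled, 1)
  for (q in qs) {
    p <- predict_curve_for_q(tr, q)
    expect_equal(p$top, 50 * q, tolerance = 1e-6)
    expect_equal(p$ec50, 2000 - 10 * q, tolerance = 1e-6)
  }
  # interpolation bracketing for the monotone Top trend
  p45 <- predict_curve_for_q(tr, 45)
  expect_gt(p45$top, 50 * 38); expect_lt(p45$top, 50 * 48)
  expect_false(tr$nonmonotone_top)
  # end-to-end: slope ratios of predicted curves reproduce the training ratios
  slope_of <- function(p) (p$top - p$bottom) / p$ec50
  fits_tot <- lapply(qs, function(q) fit_stub(four_pl_params(100, 20000, 500, 1)))
  tr_tot <- fit_param_trends(qs, fits_tot)
  ratios_train <- vapply(seq_along(qs), function(i) {
    slope_of(fits[[i]]$params) / slope_of(fits_tot[[i]]$params)
  }, numeric(1))
  ratios_pred <- vapply(qs, function(q) {
    slope_of(predict_curve_for_q(tr, q)) / slope_of(predict_curve_for_q(tr_tot, q))
  }, numeric(1))
  expect_equal(ratios_pred, ratios_train, tolerance = 0.01)
})

test_that("fit_param_trends flags a decreasing Top trend and checks inputs", {
  qs <- c(25, 38, 48, 55)
  fits_dec <- lapply(qs, function(q) fit_stub(four_pl_params(0, 5000 - 20 * q, 500, 1)))
  tr <- fit_param_trends(qs, fits_dec)
  expect_true(tr$nonmonotone_top)
  expect_error(fit_param_trends(qs[1:2], fits_dec[1:2]), ">= 3")
  bad <- fits_dec; bad[[2]]$converged <- FALSE
  expect_error(fit_param_trends(qs, bad), "converged")
})

test_that("calibration models round-trip losslessly through YAML", {
  q <- c(19, 25, 32, 38, 44, 48, 55, 72)
  set.seed(5)
  m <- select_regression_model(q, 0.5 + 0.1 * q + rnorm(8, 0, 0.05))
  path <- tempfile(fileext = ".yaml")
  write_calibration(m, path)
  m2 <- read_calibration(path)
  expect_equal(m2$family, m$family)
  expect_equal(m2$a, m$a, tolerance = 1e-15)
  expect_equal(m2$b, m$b, tolerance = 1e-15)
  expect_equal(m2$r_squared, m$r_squared, tolerance = 1e-15)
  expect_equal(m2$q_domain, m$q_domain)
  expect_equal(m2$ratio_range, m$ratio_range, tolerance = 1e-15)
  unlink(path)
})
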