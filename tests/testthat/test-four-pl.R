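test_that("evaluate_four_pl reproduces hand-computable and high-precision values", {
  # midpoint: signal at EC50 is halfway between the plateaus
  expect_equal(evaluate_four_pl(four_pl_params(0, 100, 10, 1), 10), 50)
  # degenerate flat curve
  p_flat <- four_pl_params(7, 7, 3, 2)
  expect_equal(evaluate_four_pl(p_flat, c(0, 0.5, 3, 1e6)), rep(7, 4))
  # frozen 50-digit substitution oracle for an asymmetric steep curve
  p <- four_pl_params(100, 10100, 500, 1.3)
  expect_equal(evaluate_four_pl(p, 2000), 8684.144223701331, tolerance = 1e-12)
  # limit convention at zero concentration
  expect_equal(evaluate_four_pl(p, 0), 100)
  # invalid parameters are rejected
  expect_error(four_pl_params(0, 100, -1, 1), "ec50")
  expect_error(four_pl_params(0, 100, 10, 0), "hillslope")
  expect_error(four_pl_params(NA, 100, 10, 1), "finite")
})

test_that("evaluate_four_pl is monotone non-decreasing for Top >= Bottom, Hill > 0", {
  set.seed(11)
  for (i in 1:20) {
    b <- runif(1, 0, 500)
    p <- four_pl_params(b, b + runif(1, 0, 5e4), runif(1, 10, 5000),
                        runif(1, 0.3, 3))
    y <- evaluate_four_pl(p, seq(0, 10 * p$ec50, length.out = 200))
    expect_true(all(diff(y) >= -1e-9 * max(abs(y))))
  }
})

test_that("fit_four_pl recovers noiseless parameters and is order-invariant", {
  truth <- four_pl_params(100, 10000, 500, 1)
  conc <- c(5, 15, 50, 150, 500, 1500, 5000, 15000)
  ser <- make_series(truth, conc)
  fit <- fit_four_pl(ser)
  expect_true(fit$converged)
  for (nm in names(truth)) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-6)
  }
  # idempotence: refitting the fitted curve's own predictions
  ser2 <- make_series(fit$params, conc)
  fit2 <- fit_four_pl(ser2)
  for (nm in names(truth)) {
    expect_equal(fit2$params[[nm]], fit$params[[nm]], tolerance = 1e-8)
  }
  # point ordering must not matter
  perm <- sample(nrow(ser))
  ser_perm <- dose_response_series("fix", "polyq", ser$concentration[perm],
                                   ser$signal[perm])
  fit3 <- fit_four_pl(ser_perm)
  expect_equal(fit3$params$ec50, fit$params$ec50, tolerance = 1e-8)
})

test_that("fit_four_pl input contracts hold", {
  truth <- four_pl_params(100, 10000, 500, 1)
  expect_error(fit_four_pl(make_series(truth, c(1, 10, 100, 1000))),
               "5 distinct")
  ser <- make_series(truth, c(5, 50, 500, 5000, 5e4))
  ser$signal[1] <- -1
  expect_error(fit_four_pl(ser), "1/Y\\^2")
})

test_that("fitted weighted SSE beats a dense grid search around the truth", {
  truth <- four_pl_params(200, 8000, 400, 1.2)
  conc <- c(10, 30, 100, 300, 1000, 3000)
  set.seed(42)
  sig <- evaluate_four_pl(truth, conc) * exp(rnorm(6, 0, 0.05))
  ser <- dose_response_series("g", "polyq", conc, sig)
  fit <- fit_four_pl(ser)
  w <- 1 / sig^2
  grid_sse <- Inf
  for (b in seq(150, 250, length.out = 7))
    for (t in seq(7000, 9000, length.out = 7))
      for (e in seq(300, 500, length.out = 7))
        for (h in seq(0.9, 1.5, length.out = 7)) {
          yh <- evaluate_four_pl(four_pl_params(b, t, e, h), conc)
          grid_sse <- min(grid_sse, sum(w * (sig - yh)^2))
        }
  expect_lte(fit$weighted_sse, grid_sse + 1e-12)
  # and beats (or equals) the generating parameters
  y_true <- evaluate_four_pl(truth, conc)
  expect_lte(fit$weighted_sse, sum(w * (sig - y_true)^2) + 1e-12)
})

test_that("signal rescaling scales plateaus and slope, leaving EC50/Hill/ratio fixed", {
  truth <- four_pl_params(100, 10000, 500, 1)
  conc <- c(2, 5, 10, 25, 60, 150, 400, 1000, 3000)
  set.seed(9)
  sig <- evaluate_four_pl(truth, conc) * exp(rnorm(length(conc), 0, 0.02))
  s1 <- dose_response_series("a", "polyq", conc, sig)
  s2 <- dose_response_series("a", "polyq", conc, 3.7 * sig)
  f1 <- fit_four_pl(s1); f2 <- fit_four_pl(s2)
  expect_equal(f2$params$bottom, 3.7 * f1$params$bottom, tolerance = 1e-4)
  expect_equal(f2$params$top, 3.7 * f1$params$top, tolerance = 1e-4)
  expect_equal(f2$params$ec50, f1$params$ec50, tolerance = 1e-4)
  expect_equal(f2$params$hillslope, f1$params$hillslope, tolerance = 1e-4)
  l1 <- determine_linear_range(s1, f1); l2 <- determine_linear_range(s2, f2)
  expect_equal(l2$slope, 3.7 * l1$slope, tolerance = 1e-6)
  r <- slope_ratio(l2, l1)
  expect_equal(r$ratio, 3.7, tolerance = 1e-6)
})

test_that("determine_linear_range accepts proportional data over the full range", {
  conc <- c(1, 2, 4, 8, 16, 32)
  ser <- dose_response_series("p", "polyq", conc, 12.5 * conc)
  sl <- determine_linear_range(ser, fit_stub(four_pl_params(0, 1e6, 1e5, 1)))
  expect_equal(sl$slope, 12.5, tolerance = 1e-9)
  expect_equal(c(sl$window_lo, sl$window_hi), c(1, 32))
  expect_equal(sl$n_points_used, 6L)
})

test_that("linear-range slope approaches Top/EC50 well below the EC50", {
  p <- four_pl_params(0, 10000, 1000, 1)
  conc <- c(1, 2, 5, 10)
  ser <- make_series(p, conc)
  sl <- determine_linear_range(ser, fit_stub(p))
  expect_equal(sl$slope, 10, tolerance = 0.01)
})

test_that("saturating standards are excluded from the linear window", {
  p <- four_pl_params(0, 10000, 1000, 1)
  conc_lin <- c(1, 2, 5, 10)
  ser_lin <- dose_response_series("s", "polyq", conc_lin, 10 * conc_lin)
  sl_lin <- determine_linear_range(ser_lin, fit_stub(p))
  conc_all <- c(conc_lin, 5000, 10000)
  sig_all <- c(10 * conc_lin, evaluate_four_pl(p, c(5000, 10000)))
  ser_all <- dose_response_series("s", "polyq", conc_all, sig_all)
  sl_all <- determine_linear_range(ser_all, fit_stub(p))
  expect_lt(sl_all$window_hi, 5000)
  expect_equal(sl_all$slope, sl_lin$slope, tolerance = max(sl_lin$slope_sd, 1e-9))
  # a series with no proportional window errors informatively
  conc_sat <- c(3000, 5000, 8000, 12000, 20000)
  ser_sat <- make_series(p, conc_sat)
  expect_error(determine_linear_range(ser_sat, fit_stub(p)), "no linear")
})

test_that("replicate duplication leaves the linear-range slope unchanged", {
  conc <- c(1, 2, 4, 8)
  set.seed(3)
  sig <- 12.5 * conc * exp(rnorm(4, 0, 0.02))
  ser <- dose_response_series("d", "polyq", conc, sig)
  ser_dup <- dose_response_series("d", "polyq", c(conc, 4), c(sig, sig[3]))
  f <- fit_stub(four_pl_params(0, 1e6, 1e5, 1))
  s1 <- determine_linear_range(ser, f)
  s2 <- determine_linear_range(ser_dup, f)
  expect_equal(s2$slope, s1$slope, tolerance = s1$slope_sd)
})

test_that("slope_ratio propagates uncertainty by the quadrature rule", {
  mk <- function(s, sd) list(slope = s, slope_sd = sd)
  r0 <- slope_ratio(mk(20, 0), mk(10, 0))
  expect_equal(r0$ratio, 2); expect_equal(r0$sd, 0)
  # A/A symmetry
  rs <- slope_ratio(mk(347.4, 12), mk(347.4, 12))
  expect_equal(rs$ratio, 1)
  expect_equal(rs$sd, sqrt(2) * 12 / 347.4)
  expect_error(slope_ratio(mk(20, 1), mk(0, 1)), "denominator")
  # Monte-Carlo oracle for a realistic slope pair
  r <- slope_ratio(mk(347.4, 12), mk(81.2, 3))
  set.seed(77)
  draws <- rnorm(1e6, 347.4, 12) / rnorm(1e6, 81.2, 3)
  expect_equal(r$ratio, 347.4 / 81.2, tolerance = 1e-12)
  expect_equal(r$sd, sd(draws), tolerance = 0.02)
})
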