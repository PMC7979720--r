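test_that("fit_linear reproduces exact lines and rejects degenerate input", {
  x <- seq(0, 3, by = 0.1)
  f <- fit_linear(x, 4 * x + 45)
  expect_equal(f$slope, 4)
  expect_equal(f$intercept, 45)
  expect_equal(f$r2, 1)
  expect_equal(f$rss, 0, tolerance = 1e-20)
  # slope(x,y) = 1/slope(y,x) only at r2 = 1, verified on the exact line
  g <- fit_linear(4 * x + 45, x)
  expect_equal(g$slope, 1 / f$slope)
  expect_error(fit_linear(rep(1, 10), rnorm(10)), "singular")
  expect_error(fit_linear(1:2, 1:2), ">= 3")
})

test_that("piecewise fit splits regions half-open at the breakpoint", {
  x <- seq(0, 2, by = 0.01)
  y <- 100 * x + 500
  pw <- fit_piecewise(x, y)
  expect_equal(pw$s1_slope, 100, tolerance = 1e-9)
  expect_equal(pw$s2_slope, 100, tolerance = 1e-9)
  # boundary points belong to S2: [0, 0.75) and [0.75, 2]
  expect_equal(pw$n1, sum(x < 0.75))
  expect_equal(pw$n2, sum(x >= 0.75))
  expect_error(fit_piecewise(c(0.1, 0.2, 0.3, 0.8, 0.9), rnorm(5)), "S2")
  # equal generating slopes come back equal under noise
  set.seed(3)
  xn <- runif(400, 0, 2)
  yn <- 80 * xn + 300 + rnorm(400, 0, 5)
  pn <- fit_piecewise(xn, yn)
  expect_equal(pn$s1_slope, pn$s2_slope, tolerance = 0.15)
})

test_that("piecewise fit recovers the generating slopes under noise", {
  set.seed(9)
  x <- runif(500, 0.15, 2)
  y <- 511 + 189 * (pmin(x, 0.75) - 0.15) + 55 * pmax(0, x - 0.75) +
    rnorm(500, 0, 10)
  pw <- fit_piecewise(x, y)
  expect_equal(pw$s1_slope, 189, tolerance = 0.10)
  expect_equal(pw$s2_slope, 55, tolerance = 0.10 * 189 / 55)
})

test_that("delta-BIC selects the generating pressure and zeroes the null", {
  set.seed(21)
  pb <- runif(300, 0, 3)
  picas <- sample(seq(0, 3, by = 0.25), 300, replace = TRUE)
  pt <- pb - picas
  y <- 200 * pt + 500 + rnorm(300, 0, 5)
  cmp <- delta_bic(y, list(p_b = pb, p_icas = picas, p_t = pt))
  expect_identical(attr(cmp, "best"), "p_t")
  expect_lt(cmp$delta_bic[cmp$model == "p_t"], -10)
  expect_identical(cmp$delta_bic[cmp$model == "null"], 0)
  # pure noise: no candidate earns meaningful support over the null
  y0 <- rnorm(300)
  cmp0 <- delta_bic(y0, list(p_b = pb, p_icas = picas, p_t = pt))
  expect_true(all(cmp0$delta_bic > -log(300)))
  # invariant to adding a constant to the response
  cmp_shift <- delta_bic(y + 1e4, list(p_b = pb, p_icas = picas, p_t = pt))
  expect_equal(cmp_shift$delta_bic, cmp$delta_bic, tolerance = 1e-8)
  expect_warning(delta_bic(y, list(p_b = pb, flat = rep(1, 300))),
                 "constant")
})

test_that("BIC differences agree with a brute-force likelihood oracle", {
  # oracle: full profiled Gaussian log-likelihood, BIC = -2 ll + k log n
  oracle_bic <- function(y, X) {
    fit <- stats::lm(y ~ X - 1)
    n <- length(y)
    rss <- sum(stats::resid(fit)^2)
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    -2 * ll + (ncol(X) + 1) * log(n)
  }
  set.seed(33)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    x <- runif(n, 0, 3)
    y <- 3 * x + rnorm(n)
    cmp <- delta_bic(y, list(p_b = x))
    d_oracle <- oracle_bic(y, cbind(1, x)) - oracle_bic(y, cbind(rep(1, n)))
    expect_equal(cmp$delta_bic[cmp$model == "p_b"], d_oracle,
                 tolerance = 1e-9)
    # and the same difference via stats::BIC on lm fits
    d_stats <- stats::BIC(stats::lm(y ~ x)) - stats::BIC(stats::lm(y ~ 1))
    expect_equal(cmp$delta_bic[cmp$model == "p_b"], d_stats,
                 tolerance = 1e-9)
  }
})

test_that("pipeline fits identify p_t for f_o and p_b for SL", {
  fits <- small_run()$analysis$fits
  expect_identical(attr(fits$bic_f0, "best"), "p_t")
  expect_identical(attr(fits$bic_sl, "best"), "p_b")
  expect_equal(fits$f0_piecewise$s1_slope, 189, tolerance = 0.05)
  expect_equal(fits$sl_linear$slope, 4, tolerance = 0.15)
})
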