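#' Ordinary least-squares line fit
#'
#' Thin wrapper around [stats::lm()] returning the quantities the pipeline
#' reports: slope, intercept, r-squared and residual sum of squares.
#'
#' @param x Predictor (pressure, kPa).
#' @param y Response (feature).
#' @return List: `slope`, `intercept`, `r2`, `rss`, `n`.
#' @export
fit_linear <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 points, got ", length(x))
  if (stats::sd(x) == 0) stop("singular design: constant predictor")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       r2 = if (tss > 0) 1 - rss / tss else NA_real_, rss = rss,
       n = length(x))
}

#' Piecewise two-region slope fit of a feature against transmural pressure
#'
#' Fits two independent ordinary least-squares lines over the low- and
#' high-pressure regimes, with no continuity constraint: region S1 covers
#' `[0, breakpoint)` and S2 `[breakpoint, upper_limit]` (the breakpoint is
#' assigned to S2; half-open split, configurable via the arguments). Points
#' outside `[0, upper_limit]` are dropped.
#'
#' @param x Transmural pressure values (kPa).
#' @param y Feature values (e.g. f_o in Hz).
#' @param breakpoint Region boundary (kPa), default 0.75.
#' @param upper_limit Upper fit limit (kPa), default 2.
#' @return A `piecewise_fit` list: `s1_slope`, `s2_slope`, `s1_intercept`,
#'   `s2_intercept`, `n1`, `n2`, `r2_1`, `r2_2`, `breakpoint`,
#'   `upper_limit`.
#' @export
fit_piecewise <- function(x, y, breakpoint = 0.75, upper_limit = 2.0) {
  stopifnot(breakpoint > 0, breakpoint < upper_limit)
  keep <- is.finite(x) & is.finite(y) & x >= 0 & x <= upper_limit
  x <- x[keep]; y <- y[keep]
  s1 <- x < breakpoint
  if (sum(s1) < 3L)
    stop("insufficient points in region S1 [0, ", breakpoint, "): ",
         sum(s1))
  if (sum(!s1) < 3L)
    stop("insufficient points in region S2 [", breakpoint, ", ",
         upper_limit, "]: ", sum(!s1))
  f1 <- fit_linear(x[s1], y[s1])
  f2 <- fit_linear(x[!s1], y[!s1])
  structure(list(s1_slope = f1$slope, s2_slope = f2$slope,
                 s1_intercept = f1$intercept, s2_intercept = f2$intercept,
                 n1 = f1$n, n2 = f2$n, r2_1 = f1$r2, r2_2 = f2$r2,
                 breakpoint = breakpoint, upper_limit = upper_limit),
            class = "piecewise_fit")
}

gaussian_bic <- function(rss, n, k_mean) {
  # profiled-Gaussian BIC up to the additive n*log(2*pi) + n term, which
  # cancels in differences; k = mean parameters + 1 for the variance
  n * log(rss / n) + (k_mean + 1) * log(n)
}

#' Delta-BIC selection of the driving pressure
#'
#' Fits `y ~ 1 + p` for every candidate pressure series and the
#' intercept-only null, computes the Gaussian BIC
#' `n log(RSS/n) + k log(n)` for each, and reports
#' `delta BIC = BIC(model) - BIC(null)`. The most negative delta BIC wins;
#' ties within 1e-9 are broken by the fixed precedence
#' `p_t > p_b > p_icas` (then input order).
#'
#' @param y Response series.
#' @param predictors Named list of pressure series, each the same length as
#'   `y` (n >= 10). Constant predictors are skipped with a warning.
#' @return A `bic_comparison` data frame: `model`, `bic`, `delta_bic`, with
#'   attribute `best`.
#' @export
delta_bic <- function(y, predictors) {
  stopifnot(is.list(predictors), length(predictors) >= 1L,
            !is.null(names(predictors)))
  keep <- Reduce(`&`, lapply(predictors, is.finite), is.finite(y))
  y <- y[keep]
  predictors <- lapply(predictors, `[`, keep)
  n <- length(y)
  if (n < 10L) stop("need n >= 10 complete cases, got ", n)
  rss_null <- sum((y - mean(y))^2)
  bic_null <- gaussian_bic(rss_null, n, 1)
  rows <- data.frame(model = "null", bic = bic_null, delta_bic = 0)
  for (nm in names(predictors)) {
    p <- predictors[[nm]]
    if (stats::sd(p) == 0) {
      warning("skipping constant predictor '", nm, "'")
      next
    }
    f <- fit_linear(p, y)
    bic <- gaussian_bic(f$rss, n, 2)
    rows <- rbind(rows, data.frame(model = nm, bic = bic,
                                   delta_bic = bic - bic_null))
  }
  precedence <- c("p_t", "p_b", "p_icas")
  rank <- match(rows$model, precedence, nomatch = length(precedence) + 1L)
  ord <- order(round(rows$delta_bic / 1e-9) * 1e-9, rank)
  best <- rows$model[ord[1L]]
  structure(rows, class = c("bic_comparison", "data.frame"), best = best)
}
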