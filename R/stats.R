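#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of x and y after least-squares
#' projection onto the covariates plus an intercept; with no covariates
#' this is the plain correlation. p from a t distribution with
#' `n - n_covariates - 2` df.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame / matrix of covariates, or `NULL`.
#' @return list `r`, `r2`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  stopifnot(n > k + 2)
  if (k > 0) {
    Z <- cbind(1, as.matrix(covariates))
    if (qr(Z)$rank < ncol(Z)) {
      stop("collinear covariates (condition number ",
           format(kappa(Z), digits = 3), ")")
    }
    x <- stats::lm.fit(Z, x)$residuals
    y <- stats::lm.fit(Z, y)$residuals
  }
  r <- stats::cor(x, y)
  df <- n - k - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, r2 = r^2, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Binomial proportion with exact CI and test against chance
#'
#' Clopper-Pearson interval and an exact binomial test against the chance
#' rate (default 0.05, the shuffle significance level).
#'
#' @param k successes; `n` trials; `level` CI level; `chance` null rate.
#' @return list `p_hat`, `lo`, `hi`, `p_value`.
#' @export
binomial_proportion_ci <- function(k, n, level = 0.95, chance = 0.05) {
  stopifnot(k >= 0, k <= n)
  if (n == 0) return(list(p_hat = NA_real_, lo = NA_real_, hi = NA_real_,
                          p_value = NA_real_))
  bt <- stats::binom.test(k, n, p = chance, conf.level = level)
  list(p_hat = k / n, lo = bt$conf.int[1], hi = bt$conf.int[2],
       p_value = bt$p.value)
}

#' One-sample t-test of a mean against mu0
#'
#' @param values numeric vector (n >= 2); `mu0` the null mean.
#' @return list `t`, `p`, `mean`, `degenerate` (TRUE when the sample has
#'   zero variance, in which case t and p are NA).
#' @export
one_sample_t <- function(values, mu0 = 0) {
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0)
    return(list(t = NA_real_, p = NA_real_, mean = mean(values),
                degenerate = TRUE))
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), p = tt$p.value, mean = mean(values),
       degenerate = FALSE)
}

#' Ordinary least squares with r-squared
#'
#' @param x,y numeric vectors, n >= 3.
#' @return list `r2`, `p` (slope p), `slope`, `intercept`, `n`.
#' @export
linreg_r2 <- function(x, y) {
  stopifnot(length(x) >= 3)
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(r2 = s$r.squared, p = s$coefficients["x", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)["x"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       n = length(x))
}

#' Fisher z comparison of two independent correlations
#'
#' Used to compare PRE vs POST coupling correlations; the comparison test
#' is not uniquely determined by the source analyses and this choice is an
#' assumption of the package.
#'
#' @param r1,r2 correlations; `n1,n2` their sample sizes.
#' @return list `z`, `p` (two-sided).
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  z1 <- atanh(r1); z2 <- atanh(r2)
  z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
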