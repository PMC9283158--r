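# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the normal-equations solver checks the QR fit,
# and the potential-outcome simulator checks the closed-form natural effects.

# Explicit normal-equations OLS: beta = (X'X)^{-1} X'y, vcov = s^2 (X'X)^{-1}.
oracle_ols <- function(x, y) {
  xtx_inv <- solve(crossprod(x))
  beta <- drop(xtx_inv %*% crossprod(x, y))
  resid <- y - drop(x %*% beta)
  dof <- length(y) - ncol(x)
  s2 <- sum(resid^2) / dof
  list(coefficients = beta, covariance = s2 * xtx_inv,
       residual_variance = s2, dof_residual = dof)
}

# Potential-outcome simulation of the four natural effects for linear
# mediator/outcome models: draws M(x) from the fitted mediator model
# (including its residual distribution) and averages Y(x, M(x')) over draws.
# Returns estimates plus Monte Carlo standard errors.
oracle_natural_effects <- function(a, b, c_prime, h, mu0, sd_m,
                                   x0, x1, n_draws = 1e6) {
  m0 <- mu0 + a * x0 + rnorm(n_draws, 0, sd_m)
  m1 <- mu0 + a * x1 + rnorm(n_draws, 0, sd_m)
  yfun <- function(x, m) c_prime * x + b * m + h * x * m
  contrast <- function(v) c(est = mean(v), se = sd(v) / sqrt(n_draws))
  list(
    pnde = contrast(yfun(x1, m0) - yfun(x0, m0)),
    tnde = contrast(yfun(x1, m1) - yfun(x0, m1)),
    pnie = contrast(yfun(x0, m1) - yfun(x0, m0)),
    tnie = contrast(yfun(x1, m1) - yfun(x1, m0)),
    total = contrast(yfun(x1, m1) - yfun(x0, m0))
  )
}

# Minimal generator for plain mediation data without the cohort dressing:
# X ~ N(0,1) (+ optional confounder), M = a X + ..., Y = c' X + b M + h X M + ...
sim_simple <- function(n, a, b, c_prime, h = 0, sd_m = 1, sd_y = 1,
                       seed = NULL, confounder = FALSE,
                       u_on_m = 0, u_on_y = 0, u_on_x = 0) {
  gen <- function() {
    u <- rnorm(n)
    x <- rnorm(n) + u_on_x * u
    m <- a * x + u_on_m * u + rnorm(n, 0, sd_m)
    y <- c_prime * x + b * m + h * x * m + u_on_y * u + rnorm(n, 0, sd_y)
    d <- tibble::tibble(x = x, m = m, y = y)
    if (confounder) d$u <- u
    d
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

path_est <- function(paths, label) {
  paths$paths$estimate[match(label, paths$paths$path)]
}
path_se <- function(paths, label) {
  paths$paths$std.error[match(label, paths$paths$path)]
}

# Small decision grid + config used by engine tests (two covariates only, so
# runs stay fast).
small_points <- function() {
  list(
    decision_point("determinant", c("continuous")),
    decision_point("confounder_set", c("tiny")),
    decision_point("confounder_strategy", c("a_priori")),
    decision_point("age_group", c("all")),
    decision_point("interaction", c("none", "pure", "total"))
  )
}
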