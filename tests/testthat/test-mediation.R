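test_that("path coefficients are recovered at large n", {
  d <- sim_simple(20000, a = 0.5, b = 0.4, c_prime = 0.2, seed = 21)
  p <- estimate_paths(d, "x", "m", "y")
  expect_lt(abs(path_est(p, "a") - 0.5), 3 * path_se(p, "a"))
  expect_lt(abs(path_est(p, "b") - 0.4), 3 * path_se(p, "b"))
  expect_lt(abs(path_est(p, "c_prime") - 0.2), 3 * path_se(p, "c_prime"))
  ab <- path_est(p, "a") * path_est(p, "b")
  se_ab <- sqrt(path_est(p, "b")^2 * path_se(p, "a")^2 +
                  path_est(p, "a")^2 * path_se(p, "b")^2)
  expect_lt(abs(ab - 0.2), 3 * se_ab)
})

test_that("a null determinant-mediator path yields ab near zero", {
  d <- sim_simple(20000, a = 0, b = 0.4, c_prime = 0.2, seed = 22)
  p <- estimate_paths(d, "x", "m", "y")
  expect_lt(abs(path_est(p, "a")), 3 * path_se(p, "a"))
})

test_that("product and difference of coefficients agree without interaction", {
  # algebraic identity of linear OLS whenever Eqs. 1 and 3 share covariates
  for (seed in 1:5) {
    d <- sim_simple(80, a = 0.7, b = -0.6, c_prime = 0.4, seed = seed,
                    confounder = TRUE, u_on_m = 0.5, u_on_y = 0.5)
    p <- estimate_paths(d, "x", "m", "y", covariates_outcome = "u")
    ab <- path_est(p, "a") * path_est(p, "b")
    diff <- path_est(p, "c") - path_est(p, "c_prime")
    expect_lt(abs(ab - diff), 1e-8 * max(1, abs(ab)))
  }
})

test_that("rescaling the mediator leaves the product of coefficients invariant", {
  d <- sim_simple(500, a = 0.5, b = 0.4, c_prime = 0.2, seed = 31)
  p1 <- estimate_paths(d, "x", "m", "y")
  d$m <- d$m * 4.2
  p2 <- estimate_paths(d, "x", "m", "y")
  expect_equal(path_est(p1, "a") * path_est(p1, "b"),
               path_est(p2, "a") * path_est(p2, "b"), tolerance = 1e-10)
  expect_equal(path_est(p2, "a"), path_est(p1, "a") * 4.2, tolerance = 1e-10)
})

test_that("proportion mediated handles arithmetic, zero and inconsistent cases", {
  mk <- function(a, b, c, cp) {
    # assemble a minimal paths object by hand
    structure(list(paths = tibble::tibble(
      path = c("c", "a", "b", "c_prime"), term = ".x",
      estimate = c(c, a, b, cp), std.error = 1, statistic = 0, p.value = 1
    )), class = "mediation_paths")
  }
  p <- proportion_mediated(mk(a = 1, b = 1, c = 5, cp = 4))
  expect_equal(p$proportion, 20)
  expect_true(p$defined)
  expect_false(p$inconsistent)

  expect_equal(proportion_mediated(mk(a = 0, b = 1, c = 5, cp = 5))$proportion, 0)

  und <- proportion_mediated(mk(a = 1, b = 1, c = 0, cp = -1))
  expect_false(und$defined)
  expect_true(is.na(und$proportion))

  # opposing direct and indirect effects push the proportion above 100%
  inc <- proportion_mediated(mk(a = 1, b = 1, c = 0.5, cp = -0.5))
  expect_gt(inc$proportion, 100)
  expect_true(inc$inconsistent)
})

test_that("causal steps requires all three significant paths and attenuation", {
  d <- sim_simple(2000, a = 0.6, b = 0.6, c_prime = 0.3, seed = 41)
  p <- estimate_paths(d, "x", "m", "y")
  expect_true(causal_steps_verdict(p))

  # a = 0 generator: verdict false (the a path is null)
  d0 <- sim_simple(2000, a = 0, b = 0.6, c_prime = 0.3, seed = 42)
  expect_false(causal_steps_verdict(estimate_paths(d0, "x", "m", "y")))
})

test_that("inconsistent mediation defeats causal steps but not the CI verdict", {
  # positive ab, negative c' of similar magnitude: total effect ~ 0
  d <- sim_simple(1500, a = 0.5, b = 0.5, c_prime = -0.25, seed = 43)
  p <- estimate_paths(d, "x", "m", "y")
  expect_false(coefficient_summary(p$fits$total, ".x")$significant)
  expect_false(causal_steps_verdict(p))
  ci <- monte_carlo_ci(
    list(med = p$fits$mediator$coefficients, out = p$fits$outcome$coefficients),
    list(med = p$fits$mediator$covariance, out = p$fits$outcome$covariance),
    function(dr) dr$med[, ".x"] * dr$out[, ".m"], seed = 1
  )
  expect_true(mediation_verdict_ci(ci))
})

test_that("simple slopes reproduce the generating moderated coefficients", {
  d <- withr::with_seed(51, {
    z <- rbinom(20000, 1, 0.4)
    x <- rnorm(20000)
    a_i <- ifelse(z == 1, 0.1, 0.5)
    m <- a_i * x + rnorm(20000)
    y <- 0.2 * x + 0.4 * m + rnorm(20000)
    tibble::tibble(x = x, m = m, y = y, z = z)
  })
  s0 <- simple_slopes(d, "x", "m", "y", "z", 0)
  s1 <- simple_slopes(d, "x", "m", "y", "z", 1)
  expect_lt(abs(path_est(s0, "a") - 0.5), 3 * path_se(s0, "a"))
  expect_lt(abs(path_est(s1, "a") - 0.1), 3 * path_se(s1, "a"))
  expect_true(s0$moderated)
})

test_that("slopes at level 0 equal the pooled main effects exactly", {
  d <- withr::with_seed(52, tibble::tibble(
    x = rnorm(300), z = rbinom(300, 1, 0.5),
    m = 0.5 * x + rnorm(300), y = 0.3 * x + 0.4 * m + rnorm(300)
  ))
  s0 <- simple_slopes(d, "x", "m", "y", "z", 0)
  # refit the augmented models directly: the .x / .m main effects must match
  d$xz <- d$x * d$z
  d$mz <- d$m * d$z
  eq2 <- fit_ols(d, "m", c("x", "z", "xz"))
  expect_equal(path_est(s0, "a"), unname(eq2$coefficients["x"]),
               tolerance = 1e-12)
  eq3 <- fit_ols(d, "y", c("x", "m", "z", "xz", "mz"))
  expect_equal(path_est(s0, "b"), unname(eq3$coefficients["m"]),
               tolerance = 1e-12)
  expect_equal(path_est(s0, "c_prime"), unname(eq3$coefficients["x"]),
               tolerance = 1e-12)
})

test_that("no-moderation generator gives similar slopes at the two levels", {
  d <- withr::with_seed(53, tibble::tibble(
    x = rnorm(5000), z = rbinom(5000, 1, 0.5),
    m = 0.5 * x + rnorm(5000), y = 0.3 * x + 0.4 * m + rnorm(5000)
  ))
  s0 <- simple_slopes(d, "x", "m", "y", "z", 0)
  s1 <- simple_slopes(d, "x", "m", "y", "z", 1)
  se_diff <- sqrt(path_se(s0, "a")^2 + path_se(s1, "a")^2)
  expect_lt(abs(path_est(s0, "a") - path_est(s1, "a")), 3 * se_diff)
})

test_that("fully-interacted simple slopes approximate per-stratum refits", {
  d <- withr::with_seed(54, {
    z <- rbinom(4000, 1, 0.5)
    x <- rnorm(4000)
    m <- (0.5 - 0.3 * z) * x + rnorm(4000)
    y <- 0.2 * x + (0.4 + 0.2 * z) * m + rnorm(4000)
    tibble::tibble(x = x, m = m, y = y, z = z)
  })
  for (lev in c(0, 1)) {
    ss <- simple_slopes(d, "x", "m", "y", "z", lev)
    strat <- estimate_paths(d[d$z == lev, ], "x", "m", "y")
    for (lab in c("a", "b", "c_prime")) {
      se <- sqrt(path_se(ss, lab)^2 + path_se(strat, lab)^2)
      expect_lt(abs(path_est(ss, lab) - path_est(strat, lab)), 3 * se)
    }
  }
})

test_that("moderator validation rejects non-binary and single-level input", {
  d <- tibble::tibble(x = rnorm(30), m = rnorm(30), y = rnorm(30),
                      z = rep(0, 30), w = runif(30, 2, 3))
  expect_error(simple_slopes(d, "x", "m", "y", "w", 0), "binary")
  expect_error(simple_slopes(d, "x", "m", "y", "z", 0), "both moderator levels")
})
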