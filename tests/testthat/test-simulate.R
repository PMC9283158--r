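test_that("the generator is bit-identical under the same seed", {
  cfg <- mediation_sim_config(n = 120, seed = 5)
  d1 <- simulate_mediation_data(cfg)
  d2 <- simulate_mediation_data(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_mediation_data(cfg, seed = 6)
  expect_false(identical(d1$bmd_mg_cm2, d3$bmd_mg_cm2))
})

test_that("config validation enforces the documented bounds", {
  expect_error(mediation_sim_config(n = 10), "at least 30")
  expect_error(mediation_sim_config(missing_rate = 0.1), "0.07")
  expect_silent(mediation_sim_config(missing_rate = 0.068))
})

test_that("global-null generator yields null fitted paths", {
  cfg <- mediation_sim_config(
    n = 20000, true_a = 0, true_b = 0, true_c_prime = 0,
    true_interaction = 0, moderator_shift_a = 0,
    missing_rate = 0, seed = 101
  )
  d <- simulate_mediation_data(cfg)
  p <- estimate_paths(d, "pct_weight_change", "fat_mass_kg", "bmd_mg_cm2",
                      covariates_outcome = lasa_multiverse_config()$covariate_sets$no_hormonal)
  for (lab in c("a", "b", "c_prime")) {
    expect_lt(abs(path_est(p, lab)), 3 * path_se(p, lab))
  }
})

test_that("true a and b are recovered and ab lands on the product", {
  cfg <- mediation_sim_config(
    n = 20000, true_a = 0.5, true_b = 0.4, true_c_prime = 0.2,
    true_interaction = 0, moderator_shift_a = 0, moderator_shift_b = 0,
    residual_sd_m = 2, residual_sd_y = 5, hormonal_block = FALSE,
    missing_rate = 0, seed = 102
  )
  d <- simulate_mediation_data(cfg)
  covs <- cfg$confounders$name
  p <- estimate_paths(d, "pct_weight_change", "fat_mass_kg", "bmd_mg_cm2",
                      covariates_outcome = covs)
  expect_lt(abs(path_est(p, "a") - 0.5), 3 * path_se(p, "a"))
  expect_lt(abs(path_est(p, "b") - 0.4), 3 * path_se(p, "b"))
  ab <- path_est(p, "a") * path_est(p, "b")
  se_ab <- sqrt(path_est(p, "b")^2 * path_se(p, "a")^2 +
                  path_est(p, "a")^2 * path_se(p, "b")^2)
  expect_lt(abs(ab - 0.2), 3 * se_ab)
})

test_that("percent change, weights and missingness are mutually consistent", {
  d <- simulate_mediation_data(mediation_sim_config(n = 500, seed = 103,
                                                    missing_rate = 0.05))
  expect_equal(percent_weight_change(d$lowest_weight_kg, d$weight_kg),
               d$pct_weight_change, tolerance = 1e-10)
  expect_true(all(d$lowest_weight_kg > 0))
  affected <- c("fat_mass_kg", "bmd_mg_cm2", "alcohol_per_week",
                "walking_min_day", "vitd_25oh", "igf1")
  rate <- mean(is.na(as.matrix(d[affected])))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / (500 * 6)))
  # determinant columns stay complete
  expect_false(anyNA(d$pct_weight_change))
})

test_that("estimates approach the truth as n grows", {
  errs <- vapply(c(500, 2000, 8000), function(n) {
    est <- vapply(1:12, function(s) {
      cfg <- mediation_sim_config(n = n, true_interaction = 0,
                                  moderator_shift_a = 0,
                                  hormonal_block = FALSE, missing_rate = 0,
                                  residual_sd_m = 8, residual_sd_y = 300,
                                  seed = 1000 * s + n)
      d <- simulate_mediation_data(cfg)
      p <- estimate_paths(d, "pct_weight_change", "fat_mass_kg",
                          "bmd_mg_cm2",
                          covariates_outcome = cfg$confounders$name)
      path_est(p, "a") * path_est(p, "b")
    }, numeric(1))
    stats::median(abs(est - 0.25 * 11.7))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("adjusting for the mediator-caused hormonal block biases b downwards", {
  cfg <- mediation_sim_config(n = 20000, true_interaction = 0,
                              moderator_shift_a = 0, missing_rate = 0,
                              seed = 104)
  d <- simulate_mediation_data(cfg)
  base <- lasa_multiverse_config()$covariate_sets$no_hormonal
  full <- lasa_multiverse_config()$covariate_sets$full
  p_no <- estimate_paths(d, "pct_weight_change", "fat_mass_kg", "bmd_mg_cm2",
                         covariates_outcome = base)
  p_block <- estimate_paths(d, "pct_weight_change", "fat_mass_kg",
                            "bmd_mg_cm2", covariates_outcome = full)
  # without the block b is consistent for the truth ...
  expect_lt(abs(path_est(p_no, "b") - cfg$true_b), 3 * path_se(p_no, "b"))
  # ... with the block it is pulled below it by more than sampling error
  expect_lt(path_est(p_block, "b") + 3 * path_se(p_block, "b"),
            path_est(p_no, "b"))
})

test_that("true natural effects match the closed forms and the null contrast", {
  cfg <- mediation_sim_config(seed = 1)
  tne <- true_natural_effects(cfg)
  expect_equal(tne$estimate[tne$effect == "pnie"],
               cfg$true_a * (cfg$true_b + cfg$true_interaction * 0))
  cfg0 <- mediation_sim_config(true_interaction = 0, seed = 1)
  tne0 <- true_natural_effects(cfg0)
  expect_equal(tne0$estimate[tne0$effect == "pnie"],
               cfg0$true_a * cfg0$true_b)
  expect_equal(tne0$estimate[tne0$effect == "pnie"],
               tne0$estimate[tne0$effect == "tnie"])
  null_c <- true_natural_effects(cfg, x0 = 3, x1 = 3)
  expect_true(all(null_c$estimate == 0))
})

test_that("with interaction the true effects match the simulation oracle", {
  cfg <- mediation_sim_config(true_interaction = 0.05, seed = 2)
  tne <- true_natural_effects(cfg, x0 = 0, x1 = 1)
  sim <- withr::with_seed(105, oracle_natural_effects(
    a = cfg$true_a, b = cfg$true_b, c_prime = cfg$true_c_prime,
    h = cfg$true_interaction, mu0 = cfg$m_intercept,
    sd_m = cfg$residual_sd_m, x0 = 0, x1 = 1, n_draws = 1e6
  ))
  for (nm in c("pnde", "tnde", "pnie", "tnie", "total")) {
    expect_lt(abs(tne$estimate[tne$effect == nm] - sim[[nm]]["est"]),
              3 * sim[[nm]]["se"] + 1e-12)
  }
})
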