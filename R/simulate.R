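#' Default confounder panel for the synthetic generator
#'
#' A cohort-style panel mirroring the worked example's adjustment set:
#' anthropometry, age, lifestyle, chronic disease and medication indicators.
#' Each row declares the marginal distribution (`continuous` with `mean`/`sd`
#' or `binary` with `prob`) and the linear effects on the determinant
#' (percent weight change), the mediator (fat mass, kg) and the outcome
#' (bone mineral density, mg/cm^2). Effects act on mean-centred confounders,
#' so they shift covariances, not marginal locations.
#'
#' @return Tibble with columns `name`, `type`, `mean`, `sd`, `prob`,
#'   `effect_x`, `effect_m`, `effect_y`.
#' @export
default_confounders <- function() {
  tibble::tribble(
    ~name,                ~type,        ~mean, ~sd, ~prob, ~effect_x, ~effect_m, ~effect_y,
    "height_cm",          "continuous", 166,   6.5, NA,     0.05,      0.25,      1.5,
    "age",                "continuous",  70,   8,   NA,    -0.10,     -0.08,     -6.0,
    "smoking",            "binary",      NA,  NA,   0.25,  -1.0,      -0.8,     -15,
    "alcohol_per_week",   "continuous",   3,   3,   NA,     0.05,      0.05,     -1.0,
    "walking_min_day",    "continuous",  45,  25,   NA,    -0.02,      0.02,      0.3,
    "sports",             "binary",      NA,  NA,   0.50,  -1.0,      -0.5,      10,
    "copd",               "binary",      NA,  NA,   0.08,  -2.0,      -0.5,     -20,
    "stroke",             "binary",      NA,  NA,   0.05,   0.5,       0.3,     -10,
    "arthritis",          "binary",      NA,  NA,   0.06,   0.5,       0.2,     -15,
    "diabetes",           "binary",      NA,  NA,   0.07,   2.0,       1.5,     -10,
    "corticosteroid_use", "binary",      NA,  NA,   0.06,   0.5,       0.3,     -25,
    "estrogen_use",       "binary",      NA,  NA,   0.12,  -0.5,      -0.3,      25
  )
}

# Hormonal block: markers generated downstream of the mediator
# (H = alpha + lambda * M + e), with the residual e feeding the outcome.
# Adjusting the outcome model for these markers therefore distorts the
# mediator-outcome coefficient by -sum(gamma * lambda), while omitting them
# leaves it unbiased — the generator's encoding of posttreatment ambiguity.
hormonal_spec <- function() {
  tibble::tribble(
    ~name,        ~alpha, ~lambda, ~sd,  ~gamma,
    "shbg",        60,    -0.8,    10,   -2.5,
    "pth",          5,     0.08,    1.5, -8.0,
    "vitd_25oh",   60,    -0.5,    15,    1.2,
    "igf1",        15,     0.15,    4,    4.0,
    "albumin",     43,     0.08,    2.5,  3.0
  )
}

#' Configuration for the synthetic mediation-data generator
#'
#' Defines the ground truth of a weight-change (determinant, percent) /
#' fat-mass (mediator, kg) / bone-mineral-density (outcome, mg/cm^2)
#' mediation structure with a confounder panel, an optional hormonal block
#' downstream of the mediator, a binary-by-threshold age moderator, and small
#' completely-at-random missingness.
#'
#' The defaults are the `lasa_like` preset: n = 264 subjects (the worked
#' example's female subsample size), true paths `a` = 0.25 kg per percent,
#' `b` = 11.7 mg/cm^2 per kg (so `ab` is about 2.9 mg/cm^2 per percent, the
#' scale of the worked example's headline estimate), a small negative direct
#' effect, a weak determinant-mediator interaction, and residual noise sized
#' so the original-specification indirect effect sits near the detection
#' boundary (roughly 80% power), producing a mix of significant and
#' non-significant universes.
#'
#' @param n Number of subjects (>= 30).
#' @param true_a,true_b,true_c_prime,true_interaction True path coefficients.
#' @param moderator_shift_a,moderator_shift_b Additive change of `a` and `b`
#'   in the old-old stratum (age >= 75).
#' @param confounders Confounder panel tibble (see [default_confounders()]);
#'   may be empty (`default_confounders()[0, ]`).
#' @param hormonal_block Generate the mediator-caused hormonal markers?
#' @param residual_sd_m,residual_sd_y Residual standard deviations of the
#'   mediator and outcome models.
#' @param missing_rate Completely-at-random missingness rate applied per
#'   affected column, in `[0, 0.07]` (the worked example reports 0-6.8%).
#' @param m_intercept,y_intercept Baseline mediator and outcome levels.
#' @param x_loss_prob,x_mean_loss,x_sd_loss,x_mean_gain,x_sd_gain Mixture
#'   parameters of the percent weight-change distribution (a small weight-loss
#'   component plus a dominant gain component, so the Edwards-Nunnally
#'   categorisation yields workable decreased/stable/increased groups).
#' @param pre_weight_mean,pre_weight_sd Distribution of the lowest adult
#'   weight (kg).
#' @param seed Optional default seed used by [simulate_mediation_data()].
#' @return An object of class `mediation_sim_config` (a list).
#' @export
mediation_sim_config <- function(n = 264,
                                 true_a = 0.25, true_b = 11.7,
                                 true_c_prime = -1.5, true_interaction = 0.05,
                                 moderator_shift_a = -0.10,
                                 moderator_shift_b = 0,
                                 confounders = default_confounders(),
                                 hormonal_block = TRUE,
                                 residual_sd_m = 8, residual_sd_y = 500,
                                 missing_rate = 0.01,
                                 m_intercept = 20, y_intercept = 800,
                                 x_loss_prob = 0.10,
                                 x_mean_loss = -12, x_sd_loss = 8,
                                 x_mean_gain = 18, x_sd_gain = 10,
                                 pre_weight_mean = 62, pre_weight_sd = 8,
                                 seed = NULL) {
  if (!is.numeric(n) || n < 30) stop("n must be at least 30", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 0.07) {
    stop("missing_rate must lie in [0, 0.07]", call. = FALSE)
  }
  stopifnot(is.data.frame(confounders), residual_sd_m > 0, residual_sd_y > 0)
  structure(
    list(n = as.integer(n), true_a = true_a, true_b = true_b,
         true_c_prime = true_c_prime, true_interaction = true_interaction,
         moderator_shift_a = moderator_shift_a,
         moderator_shift_b = moderator_shift_b,
         confounders = tibble::as_tibble(confounders),
         hormonal_block = isTRUE(hormonal_block),
         residual_sd_m = residual_sd_m, residual_sd_y = residual_sd_y,
         missing_rate = missing_rate,
         m_intercept = m_intercept, y_intercept = y_intercept,
         x_loss_prob = x_loss_prob, x_mean_loss = x_mean_loss,
         x_sd_loss = x_sd_loss, x_mean_gain = x_mean_gain,
         x_sd_gain = x_sd_gain,
         pre_weight_mean = pre_weight_mean, pre_weight_sd = pre_weight_sd,
         seed = seed),
    class = "mediation_sim_config"
  )
}

#' Generate a synthetic mediation dataset
#'
#' Draws confounders first, then the determinant (percent weight change, as a
#' linear function of centred confounders plus a two-component mixture), raw
#' pre/post weights exactly consistent with the percent change, the mediator,
#' the hormonal block (downstream of the mediator), and the outcome.
#' Missingness is injected completely at random into the mediator, the
#' outcome and a few confounder columns. Bit-identical output under the same
#' seed.
#'
#' @param config A [mediation_sim_config()].
#' @param seed Integer seed; defaults to `config$seed`, which must then be
#'   set.
#' @return Tibble, one row per subject; the configuration is attached as
#'   attribute `"true_params"`.
#' @examples
#' d <- simulate_mediation_data(mediation_sim_config(n = 100, seed = 42))
#' dplyr::glimpse(d)
#' @export
simulate_mediation_data <- function(config = mediation_sim_config(),
                                    seed = config$seed) {
  stopifnot(inherits(config, "mediation_sim_config"))
  if (is.null(seed)) stop("a seed is required (argument or config$seed)",
                          call. = FALSE)
  withr::with_seed(as.integer(seed), generate_dataset(config))
}

generate_dataset <- function(config) {
  n <- config$n
  spec <- config$confounders
  conf <- purrr::pmap(spec, function(name, type, mean, sd, prob, ...) {
    if (type == "continuous") stats::rnorm(n, mean, sd)
    else stats::rbinom(n, 1, prob)
  })
  names(conf) <- spec$name
  conf <- if (nrow(spec)) tibble::as_tibble(conf) else NULL
  centred <- purrr::pmap(spec, function(name, type, mean, sd, prob, ...) {
    if (type == "continuous") conf[[name]] - mean else conf[[name]] - prob
  })
  lin <- function(effects) {
    if (nrow(spec) == 0) return(rep(0, n))
    Reduce(`+`, purrr::map2(centred, effects, `*`))
  }

  loss <- stats::rbinom(n, 1, config$x_loss_prob)
  x <- ifelse(loss == 1,
              stats::rnorm(n, config$x_mean_loss, config$x_sd_loss),
              stats::rnorm(n, config$x_mean_gain, config$x_sd_gain)) +
    lin(spec$effect_x)
  lowest <- pmax(stats::rnorm(n, config$pre_weight_mean,
                              config$pre_weight_sd), 40)
  x <- pmax(x, -80)  # weights stay positive
  current <- lowest * (1 + x / 100)

  has_age <- !is.null(conf) && "age" %in% names(conf)
  z <- if (has_age) as.numeric(conf$age >= 75) else rep(0, n)

  a_i <- config$true_a + config$moderator_shift_a * z
  m <- config$m_intercept + a_i * x + lin(spec$effect_m) +
    stats::rnorm(n, 0, config$residual_sd_m)

  horm <- NULL
  y_horm <- rep(0, n)
  if (config$hormonal_block) {
    hs <- hormonal_spec()
    resid <- purrr::pmap(hs, function(name, alpha, lambda, sd, gamma) {
      stats::rnorm(n, 0, sd)
    })
    horm <- purrr::pmap(dplyr::mutate(hs, i = dplyr::row_number()),
                        function(name, alpha, lambda, sd, gamma, i) {
      alpha + lambda * m + resid[[i]]
    })
    names(horm) <- hs$name
    horm <- tibble::as_tibble(horm)
    y_horm <- Reduce(`+`, purrr::map2(resid, hs$gamma, `*`))
  }

  b_i <- config$true_b + config$moderator_shift_b * z
  y <- config$y_intercept + config$true_c_prime * x + b_i * m +
    config$true_interaction * x * m + lin(spec$effect_y) + y_horm +
    stats::rnorm(n, 0, config$residual_sd_y)

  out <- dplyr::bind_cols(
    tibble::tibble(
      id = seq_len(n),
      lowest_weight_kg = lowest,
      weight_kg = current,
      pct_weight_change = x,
      fat_mass_kg = m,
      bmd_mg_cm2 = y
    ),
    conf,
    if (!is.null(horm)) horm
  )

  if (config$missing_rate > 0) {
    target <- intersect(
      c("fat_mass_kg", "bmd_mg_cm2", "alcohol_per_week", "walking_min_day",
        "vitd_25oh", "igf1"),
      names(out)
    )
    for (col in target) {
      miss <- stats::runif(n) < config$missing_rate
      out[[col]][miss] <- NA
    }
  }
  attr(out, "true_params") <- config
  out
}

#' True natural effects implied by a generator configuration
#'
#' Evaluates the linear-model closed forms at the generator's true
#' coefficients, with the mediator baseline at the generator's intercept
#' (confounders at their means, reference moderator stratum, age < 75).
#'
#' @param config A [mediation_sim_config()].
#' @param x0,x1 Determinant contrast; defaults 0 and 1.
#' @return Tibble with columns `effect` and `estimate` for `pnde`, `tnde`,
#'   `pnie`, `tnie` and `total`.
#' @export
true_natural_effects <- function(config, x0 = 0, x1 = 1) {
  stopifnot(inherits(config, "mediation_sim_config"))
  eff <- natural_effect_formulas(
    a = config$true_a, b = config$true_b, c_prime = config$true_c_prime,
    h = config$true_interaction, mu0 = config$m_intercept, x0 = x0, x1 = x1
  )
  tibble::tibble(effect = names(eff),
                 estimate = unlist(eff, use.names = FALSE))
}
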