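#' Configuration for a multiverse mediation run
#'
#' Maps dataset columns to their analysis roles and fixes the numerical
#' parameters shared by all universes.
#'
#' @param determinant Column holding the continuous determinant (percent
#'   weight change).
#' @param pre_weight,post_weight Columns with the raw pre/post weights (kg)
#'   backing the Edwards-Nunnally categorical determinant codings.
#' @param mediator,outcome Mediator and outcome columns.
#' @param age Column used for the binary age moderator.
#' @param age_threshold Age cut for the old-old stratum; default 75 years.
#' @param covariate_sets Named list of character vectors; names must match
#'   the option ids of the `confounder_set` decision point.
#' @param alpha Significance level for coefficient tests; default 0.05.
#' @param proportion_threshold Proportion-mediated criterion in percent;
#'   default 20.
#' @param cie_threshold Change-in-estimate selection threshold in percent;
#'   default 10.
#' @param reliability Reliability coefficient for the Edwards-Nunnally
#'   categorisation; default 0.822.
#' @param x0,x1 Determinant contrast for the continuous coding (categorical
#'   codings always contrast 1 vs 0); defaults 0 and 1.
#' @param level Confidence level of the Monte Carlo intervals; default 0.95.
#' @param n_draws Monte Carlo draws per interval; default 20000.
#' @param seed Base seed; per-universe seeds are derived from it
#'   deterministically.
#' @return An object of class `multiverse_config` (a list).
#' @export
multiverse_config <- function(determinant,
                              pre_weight = NULL, post_weight = NULL,
                              mediator, outcome,
                              age = NULL, age_threshold = 75,
                              covariate_sets = list(),
                              alpha = 0.05, proportion_threshold = 20,
                              cie_threshold = 10, reliability = 0.822,
                              x0 = 0, x1 = 1,
                              level = 0.95, n_draws = 20000, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, level > 0, level < 1,
            proportion_threshold >= 0, cie_threshold >= 0, n_draws >= 1000)
  structure(
    list(determinant = determinant, pre_weight = pre_weight,
         post_weight = post_weight, mediator = mediator, outcome = outcome,
         age = age, age_threshold = age_threshold,
         covariate_sets = covariate_sets, alpha = alpha,
         proportion_threshold = proportion_threshold,
         cie_threshold = cie_threshold, reliability = reliability,
         x0 = x0, x1 = x1, level = level, n_draws = as.integer(n_draws),
         seed = as.integer(seed)),
    class = "multiverse_config"
  )
}

#' Default configuration for the synthetic worked example
#'
#' Column roles matching [simulate_mediation_data()] output, with the full
#' confounder panel (including the hormonal block) and the reduced panel
#' (without it) as the two covariate sets.
#'
#' @param ... Overrides passed on to [multiverse_config()].
#' @export
lasa_multiverse_config <- function(...) {
  base <- c("height_cm", "age", "smoking", "alcohol_per_week",
            "walking_min_day", "sports", "copd", "stroke", "arthritis",
            "diabetes", "corticosteroid_use", "estrogen_use")
  hormonal <- c("shbg", "pth", "vitd_25oh", "igf1", "albumin")
  args <- utils::modifyList(
    list(determinant = "pct_weight_change",
         pre_weight = "lowest_weight_kg", post_weight = "weight_kg",
         mediator = "fat_mass_kg", outcome = "bmd_mg_cm2",
         age = "age", age_threshold = 75,
         covariate_sets = list(full = c(base, hormonal),
                               no_hormonal = base)),
    list(...)
  )
  do.call(multiverse_config, args)
}

#' Run the full multiverse mediation analysis
#'
#' Enumerates the universe grid, resolves each universe to a concrete model
#' specification (determinant coding, covariate set — either a priori or by
#' change-in-estimate selection —, age moderation, interaction handling),
#' collapses redundant universes, fits the mediation system per canonical
#' universe, computes Monte Carlo confidence intervals for the universe's
#' indirect and direct estimands and for the deduplicated total effects, and
#' evaluates both mediation criteria (causal steps + proportion mediated, and
#' the indirect-effect CI).
#'
#' A failure inside one universe (e.g. collinearity in a small stratum) is
#' recorded in that universe's `warnings` column; it does not abort the run.
#'
#' @param data Subject-level data frame.
#' @param points List of [decision_point()]s; default the worked-example grid
#'   [lasa_decision_points()]. Recognised point names: `determinant`,
#'   `confounder_set`, `confounder_strategy`, `age_group`, `interaction`.
#' @param config A [multiverse_config()].
#' @return A tibble of class `multiverse_result`, long over universes and
#'   effect types, with the universe grid, redundancy map, confounder
#'   selections and configuration attached as attributes.
#' @examples
#' \donttest{
#' d <- simulate_mediation_data(mediation_sim_config(n = 264, seed = 7))
#' res <- run_multiverse(d, config = lasa_multiverse_config(n_draws = 2000))
#' summarize_verdicts(res)
#' }
#' @export
run_multiverse <- function(data, points = lasa_decision_points(),
                           config = lasa_multiverse_config()) {
  stopifnot(inherits(config, "multiverse_config"))
  universes <- enumerate_universes(points)
  point_names <- setdiff(names(universes), c("universe_id", "is_original"))
  known <- c("determinant", "confounder_set", "confounder_strategy",
             "age_group", "interaction")
  unknown <- setdiff(point_names, known)
  if (length(unknown)) {
    stop("unrecognised decision point(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::as_tibble(data)
  prep <- prepare_engine_data(d, universes, config)
  resolved <- resolve_universes(prep, universes, config)
  redundancy <- detect_redundancy(universes, resolved$specs)
  canon_ids <- unique(redundancy$canonical_id)

  analyses <- purrr::map(canon_ids, function(uid) {
    analyze_universe(prep, resolved$detail[[uid]], config,
                     seed_u = derive_seed(config$seed, uid))
  })
  names(analyses) <- as.character(canon_ids)

  choice_cols <- function(uid) {
    universes[universes$universe_id == uid, c("is_original", point_names)]
  }
  per_universe <- purrr::map_dfr(universes$universe_id, function(uid) {
    canon <- redundancy$canonical_id[redundancy$universe_id == uid]
    an <- analyses[[as.character(canon)]]
    dplyr::bind_cols(
      tibble::tibble(universe_id = uid),
      choice_cols(uid),
      an$effect_rows,
      tibble::tibble(
        redundant_of = if (canon != uid) canon else NA_integer_
      )
    )
  })

  total_groups <- total_effect_specifications(universes)
  total_rows <- purrr::map_dfr(seq_len(nrow(total_groups)), function(i) {
    uid <- total_groups$universe_id[i]
    canon <- redundancy$canonical_id[redundancy$universe_id == uid]
    an <- analyses[[as.character(canon)]]
    cc <- choice_cols(uid)
    cc$interaction <- NA_character_
    cc$is_original <- total_groups$is_original[i]
    dplyr::bind_cols(
      tibble::tibble(universe_id = uid), cc, an$total_row,
      tibble::tibble(redundant_of = if (canon != uid) canon else NA_integer_)
    )
  })

  out <- dplyr::bind_rows(per_universe, total_rows) |>
    dplyr::arrange(factor(.data$effect_type,
                          levels = c("indirect", "direct", "total")),
                   .data$universe_id)
  structure(
    out,
    universes = universes,
    points = points,
    decision_names = point_names,
    redundancy = redundancy,
    selections = resolved$selections,
    config = config,
    class = c("multiverse_result", class(tibble::tibble()))
  )
}

derive_seed <- function(seed, uid) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(uid)) %% 2147483646) + 1L
}

# Precompute engine columns: categorical weight-change coding and the binary
# age moderator, as required by the options present in the grid.
prepare_engine_data <- function(d, universes, config) {
  check_columns(d, c(config$determinant, config$mediator, config$outcome))
  needs_cat <- "determinant" %in% names(universes) &&
    any(universes$determinant != "continuous")
  needs_mod <- "age_group" %in% names(universes) &&
    any(universes$age_group != "all")
  if (needs_cat) {
    if (is.null(config$pre_weight) || is.null(config$post_weight)) {
      stop("categorical determinant options require pre_weight/post_weight",
           call. = FALSE)
    }
    check_columns(d, c(config$pre_weight, config$post_weight))
    d$.category <- edwards_nunnally_classify(
      pre = d[[config$pre_weight]], post = d[[config$post_weight]],
      reliability = config$reliability
    )
  }
  if (needs_mod) {
    if (is.null(config$age)) {
      stop("age moderation options require an age column", call. = FALSE)
    }
    check_columns(d, config$age)
    d$.z <- as.numeric(d[[config$age]] >= config$age_threshold)
  }
  d
}

# Rows and determinant variable for one determinant coding.
code_determinant <- function(d, coding, config) {
  switch(
    coding,
    continuous = list(
      rows = rep(TRUE, nrow(d)),
      x = as.numeric(d[[config$determinant]]),
      x0 = config$x0, x1 = config$x1
    ),
    increased_vs_stable = list(
      rows = !is.na(d$.category) & d$.category %in% c("stable", "increased"),
      x = as.numeric(d$.category == "increased"),
      x0 = 0, x1 = 1
    ),
    decreased_vs_stable = list(
      rows = !is.na(d$.category) & d$.category %in% c("stable", "decreased"),
      x = as.numeric(d$.category == "decreased"),
      x0 = 0, x1 = 1
    ),
    stop("unknown determinant option '", coding, "'", call. = FALSE)
  )
}

# Resolve every universe: concrete covariate set (running change-in-estimate
# selection where requested, cached per determinant coding x candidate set)
# plus the coded determinant. Returns the redundancy key table, the per-
# universe detail list and the selection objects.
resolve_universes <- function(d, universes, config) {
  cie_cache <- list()
  detail <- vector("list", nrow(universes))
  specs <- vector("list", nrow(universes))
  for (i in seq_len(nrow(universes))) {
    u <- universes[i, ]
    coding <- if ("determinant" %in% names(u)) u$determinant else "continuous"
    set_id <- if ("confounder_set" %in% names(u)) u$confounder_set else
      if (length(config$covariate_sets)) names(config$covariate_sets)[1] else
        NA_character_
    strategy <- if ("confounder_strategy" %in% names(u)) u$confounder_strategy
      else "a_priori"
    age_group <- if ("age_group" %in% names(u)) u$age_group else "all"
    inter <- if ("interaction" %in% names(u)) u$interaction else "none"
    coded <- code_determinant(d, coding, config)
    base_set <- if (is.na(set_id)) character(0) else
      config$covariate_sets[[set_id]]
    if (is.null(base_set)) {
      stop("no covariate set named '", set_id, "' in the configuration",
           call. = FALSE)
    }
    if (strategy == "change_in_estimate") {
      key <- paste(coding, set_id, sep = "::")
      if (is.null(cie_cache[[key]])) {
        dd <- d[coded$rows, , drop = FALSE]
        dd$.xvar <- coded$x[coded$rows]
        cie_cache[[key]] <- change_in_estimate_select(
          dd, ".xvar", config$mediator, config$outcome,
          candidates = base_set, threshold = config$cie_threshold
        )
      }
      covs <- cie_cache[[key]]$selected
    } else if (strategy == "a_priori") {
      covs <- base_set
    } else {
      stop("unknown confounder strategy '", strategy, "'", call. = FALSE)
    }
    detail[[u$universe_id]] <- list(
      universe_id = u$universe_id, coding = coding, coded = coded,
      covariates = covs, age_group = age_group, interaction = inter
    )
    specs[[u$universe_id]] <- tibble::tibble(
      universe_id = u$universe_id, coding = coding,
      covariates = list(sort(covs)), age_group = age_group,
      interaction = inter
    )
  }
  list(specs = dplyr::bind_rows(specs), detail = detail,
       selections = cie_cache)
}

# Fit and summarise one (canonical) universe. Returns two-row effect tibble
# (indirect + direct) and a one-row total tibble; on failure, NA rows carrying
# the condition message.
analyze_universe <- function(d, spec, config, seed_u) {
  empty <- function(msg) {
    na_row <- tibble::tibble(
      estimate = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
      significant = NA, causal_steps = NA, proportion_mediated = NA_real_,
      criteria_verdict = NA, ci_verdict = NA,
      n_complete_cases = NA_integer_, warnings = msg
    )
    list(
      effect_rows = dplyr::bind_cols(
        tibble::tibble(effect_type = c("indirect", "direct"),
                       estimand = NA_character_),
        dplyr::bind_rows(na_row, na_row)
      ),
      total_row = dplyr::bind_cols(
        tibble::tibble(effect_type = "total", estimand = "c"), na_row
      )
    )
  }
  tryCatch({
    dd <- d[spec$coded$rows, , drop = FALSE]
    dd$.xvar <- spec$coded$x[spec$coded$rows]
    use_interaction <- spec$interaction != "none"
    if (spec$age_group == "all") {
      paths <- estimate_paths(dd, ".xvar", config$mediator, config$outcome,
                              covariates_outcome = spec$covariates,
                              interaction = use_interaction)
    } else {
      paths <- simple_slopes(dd, ".xvar", config$mediator, config$outcome,
                             moderator = ".z",
                             level = if (spec$age_group == "over_75") 1 else 0,
                             covariates_outcome = spec$covariates,
                             interaction = use_interaction)
    }
    universe_effect_rows(paths, spec, config, seed_u)
  }, error = function(e) empty(conditionMessage(e)))
}

universe_effect_rows <- function(paths, spec, config, seed_u) {
  x0 <- spec$coded$x0
  x1 <- spec$coded$x1
  delta <- x1 - x0
  med <- paths$fits$mediator
  out <- paths$fits$outcome
  tot <- paths$fits$total
  profile <- paths$profile
  profile[paths$terms$x] <- 0
  p_m0 <- profile[med$term_names]
  p_m0[is.na(p_m0)] <- 0
  has_h <- !is.na(paths$terms$xm)

  effect_fn <- function(kind) {
    force(kind)
    function(dr) {
      a <- dr$med[, ".x"]
      mu0 <- drop(dr$med %*% p_m0)
      b <- dr$out[, ".m"]
      cp <- dr$out[, ".x"]
      h <- if (has_h) dr$out[, ".x_m"] else 0
      switch(kind,
             ab = a * b * delta,
             c_prime = cp * delta,
             pnie = (b + h * x0) * a * delta,
             tnie = (b + h * x1) * a * delta,
             pnde = (cp + h * (mu0 + a * x0)) * delta,
             tnde = (cp + h * (mu0 + a * x1)) * delta)
    }
  }
  estimands <- switch(spec$interaction,
                      none = c(indirect = "ab", direct = "c_prime"),
                      pure = c(indirect = "pnie", direct = "pnde"),
                      total = c(indirect = "tnie", direct = "tnde"))
  blocks <- list(med = med$coefficients, out = out$coefficients)
  vcovs <- list(med = med$covariance, out = out$covariance)
  cis <- purrr::map(estimands, function(kind) {
    monte_carlo_ci(blocks, vcovs, effect_fn(kind), level = config$level,
                   n_draws = config$n_draws, seed = seed_u)
  })

  # universe-level verdicts
  ne <- natural_effects(paths, x0 = x0, x1 = x1)
  ne_get <- function(nm) ne$estimate[match(nm, ne$effect)]
  indirect_est <- cis$indirect$estimate
  total_decomp <- if (spec$interaction == "none") {
    path_coef(paths, "c") * delta
  } else {
    ne_get("total")
  }
  prop <- proportion_from(indirect_est, total_decomp,
                          direct = cis$direct$estimate)
  steps <- causal_steps_verdict(paths, alpha = config$alpha)
  criteria <- steps && prop$defined &&
    isTRUE(prop$proportion >= config$proportion_threshold)
  ci_flag <- mediation_verdict_ci(cis$indirect)

  estimand_label <- c(ab = "ab", c_prime = "c_prime", pnie = "PNIE",
                      pnde = "PNDE", tnie = "TNIE", tnde = "TNDE")
  row_of <- function(type, label, ci) {
    tibble::tibble(
      effect_type = type, estimand = estimand_label[[label]],
      estimate = ci$estimate, ci_lower = ci$lower, ci_upper = ci$upper,
      significant = ci$significant, causal_steps = steps,
      proportion_mediated = prop$proportion, criteria_verdict = criteria,
      ci_verdict = ci_flag, n_complete_cases = paths$n_obs,
      warnings = NA_character_
    )
  }
  effect_rows <- dplyr::bind_rows(
    row_of("indirect", estimands[["indirect"]], cis$indirect),
    row_of("direct", estimands[["direct"]], cis$direct)
  )

  total_ci <- monte_carlo_ci(
    list(tot = tot$coefficients), list(tot = tot$covariance),
    function(dr) dr$tot[, ".x"] * delta,
    level = config$level, n_draws = config$n_draws, seed = seed_u
  )
  total_row <- tibble::tibble(
    effect_type = "total", estimand = "c",
    estimate = total_ci$estimate, ci_lower = total_ci$lower,
    ci_upper = total_ci$upper, significant = total_ci$significant,
    causal_steps = NA, proportion_mediated = NA_real_,
    criteria_verdict = NA, ci_verdict = NA,
    n_complete_cases = paths$n_obs, warnings = NA_character_
  )
  list(effect_rows = effect_rows, total_row = total_row)
}

#' @export
print.multiverse_result <- function(x, ...) {
  n_ind <- sum(x$effect_type == "indirect")
  n_tot <- sum(x$effect_type == "total")
  n_warn <- sum(!is.na(x$warnings))
  cat("<multiverse_result> ", n_ind, " indirect + ", n_ind, " direct and ",
      n_tot, " total effect estimates",
      if (n_warn) paste0(" (", n_warn, " row(s) with warnings)") else "",
      "\n", sep = "")
  NextMethod()
}

#' Summary counts for a multiverse result
#' @param x A `multiverse_result`.
#' @param ... Unused.
#' @method glance multiverse_result
#' @export
glance.multiverse_result <- function(x, ...) {
  red <- attr(x, "redundancy")
  tibble::tibble(
    n_universes = nrow(attr(x, "universes")),
    n_indirect = sum(x$effect_type == "indirect"),
    n_direct = sum(x$effect_type == "direct"),
    n_total = sum(x$effect_type == "total"),
    n_redundant = sum(red$redundant),
    n_failed = sum(!is.na(x$warnings[x$effect_type == "indirect"]))
  )
}

#' Summarise mediation verdicts and effect signs across the multiverse
#'
#' Percentages are computed over universes (or total-effect specifications)
#' whose analysis succeeded; numerator and denominator are reported next to
#' each percentage.
#'
#' @param result A `multiverse_result`.
#' @return Tibble with columns `metric`, `numerator`, `denominator`,
#'   `percent`.
#' @export
summarize_verdicts <- function(result) {
  stopifnot(inherits(result, "multiverse_result"))
  ok <- is.na(result$warnings)
  ind <- result[result$effect_type == "indirect" & ok, ]
  dir <- result[result$effect_type == "direct" & ok, ]
  tot <- result[result$effect_type == "total" & ok, ]
  if (nrow(ind) + nrow(dir) + nrow(tot) == 0) {
    stop("no successfully analysed universes to summarise", call. = FALSE)
  }
  metric <- function(name, num, den) {
    tibble::tibble(metric = name, numerator = num, denominator = den,
                   percent = if (den > 0) 100 * num / den else NA_real_)
  }
  dplyr::bind_rows(
    metric("mediated_criteria", sum(ind$criteria_verdict, na.rm = TRUE),
           nrow(ind)),
    metric("mediated_ci", sum(ind$ci_verdict, na.rm = TRUE), nrow(ind)),
    metric("indirect_significant", sum(ind$significant, na.rm = TRUE),
           nrow(ind)),
    metric("direct_negative", sum(dir$estimate < 0, na.rm = TRUE), nrow(dir)),
    metric("direct_nonsignificant", sum(!dir$significant, na.rm = TRUE),
           nrow(dir)),
    metric("total_positive", sum(tot$estimate > 0, na.rm = TRUE), nrow(tot)),
    metric("total_significant", sum(tot$significant, na.rm = TRUE), nrow(tot))
  )
}
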