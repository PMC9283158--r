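# Shared dataset/config for engine-level tests, plus one cached full-grid run
# (Monte Carlo draws lowered: the interval properties themselves are covered
# in test-inference.R and the acceptance suite).
engine_data <- function(seed = 7, n = 264) {
  simulate_mediation_data(mediation_sim_config(n = n, seed = seed))
}
engine_config <- function(...) {
  args <- utils::modifyList(list(n_draws = 1500, seed = 3), list(...))
  do.call(lasa_multiverse_config, args)
}

# Re-derive the fitted three-equation system for one universe row of the
# worked-example grid, outside the engine: used to assert identities that the
# result table does not carry directly.
resolve_universe_fit <- function(d, uu, cfg, selections) {
  if (uu$determinant == "continuous") {
    dd <- d
    dd$.xvar <- d[[cfg$determinant]]
  } else {
    cat_ <- edwards_nunnally_classify(d[[cfg$pre_weight]],
                                      d[[cfg$post_weight]], cfg$reliability)
    lvl <- if (uu$determinant == "increased_vs_stable") "increased" else
      "decreased"
    keep <- !is.na(cat_) & cat_ %in% c("stable", lvl)
    dd <- d[keep, ]
    dd$.xvar <- as.numeric(cat_[keep] == lvl)
  }
  covs <- if (uu$confounder_strategy == "a_priori") {
    cfg$covariate_sets[[uu$confounder_set]]
  } else {
    selections[[paste(uu$determinant, uu$confounder_set,
                      sep = "::")]]$selected
  }
  use_int <- uu$interaction != "none"
  if (uu$age_group == "all") {
    estimate_paths(dd, ".xvar", cfg$mediator, cfg$outcome,
                   covariates_outcome = covs, interaction = use_int)
  } else {
    dd$.zmod <- as.numeric(dd[[cfg$age]] >= cfg$age_threshold)
    simple_slopes(dd, ".xvar", cfg$mediator, cfg$outcome, ".zmod",
                  level = if (uu$age_group == "over_75") 1 else 0,
                  covariates_outcome = covs, interaction = use_int)
  }
}

.engine_cache <- new.env(parent = emptyenv())
cached_full_run <- function() {
  if (is.null(.engine_cache$res)) {
    .engine_cache$res <- run_multiverse(engine_data(),
                                        config = engine_config())
  }
  .engine_cache$res
}
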