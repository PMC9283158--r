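#' Read a subject-level mediation dataset from CSV
#'
#' Reads the file, optionally checks and coerces columns according to a role
#' map, and attaches a per-column missingness report as attribute
#' `"missingness"`.
#'
#' @param path CSV file path.
#' @param roles Optional named list/vector mapping analysis roles (e.g.
#'   `determinant`, `mediator`, `outcome`, `age`) to column names. Mapped
#'   columns must exist and — except roles named in `categorical_roles` — be
#'   numeric; offending rows are reported by index.
#' @param categorical_roles Roles whose columns are treated as categorical.
#' @return A tibble.
#' @export
read_mediation_data <- function(path, roles = NULL,
                                categorical_roles = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (anyDuplicated(header)) {
    stop("duplicated column name(s) in ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(roles)) {
    roles <- unlist(roles)
    missing_cols <- setdiff(unname(roles), names(d))
    if (length(missing_cols)) {
      stop("mapped column(s) not present: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (role in names(roles)) {
      col <- roles[[role]]
      if (role %in% categorical_roles) {
        d[[col]] <- factor(d[[col]])
      } else if (!is.numeric(d[[col]])) {
        coerced <- suppressWarnings(as.numeric(d[[col]]))
        bad <- which(!is.na(d[[col]]) & is.na(coerced))
        if (length(bad)) {
          stop("non-numeric value(s) in numeric role '", role, "' (column '",
               col, "') at row(s) ",
               paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
        }
        d[[col]] <- coerced
      }
    }
  }
  n_miss <- vapply(d, function(col) sum(is.na(col)), integer(1),
                   USE.NAMES = FALSE)
  miss <- tibble::tibble(
    column = names(d),
    n_missing = n_miss,
    pct_missing = round(100 * n_miss / nrow(d), 2)
  )
  attr(d, "missingness") <- miss
  d
}

# Fixed float formatting (6 significant digits) so result files are
# byte-reproducible across runs.
format_numeric_cols <- function(d) {
  dplyr::mutate(d, dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_,
             formatC(.x, digits = 6, format = "g"))
  ))
}

result_column_order <- function(result) {
  fixed_head <- c("universe_id", "is_original")
  fixed_tail <- c("effect_type", "estimand", "estimate", "ci_lower",
                  "ci_upper", "significant", "causal_steps",
                  "proportion_mediated", "criteria_verdict", "ci_verdict",
                  "n_complete_cases", "redundant_of", "warnings")
  c(fixed_head, attr(result, "decision_names"), fixed_tail)
}

#' Build a run manifest for a multiverse result
#'
#' Fingerprints the configuration, data and seed so every output file can be
#' traced to the run that produced it.
#'
#' @param result A `multiverse_result`.
#' @param data The analysed dataset (optional; enables the data fingerprint).
#' @return Named list with `manifest_id`, `config_hash`, `data_fingerprint`,
#'   `seed`, `package_version`, `timestamp_utc` and `n_warnings`.
#' @export
run_manifest <- function(result, data = NULL) {
  stopifnot(inherits(result, "multiverse_result"))
  config <- attr(result, "config")
  config_hash <- rlang::hash(unclass(config))
  data_fingerprint <- if (is.null(data)) NA_character_ else
    rlang::hash(as.data.frame(data))
  list(
    manifest_id = rlang::hash(list(config_hash, data_fingerprint,
                                   config$seed)),
    config_hash = config_hash,
    data_fingerprint = data_fingerprint,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("medmultiverse")),
    timestamp_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    n_warnings = sum(!is.na(result$warnings))
  )
}

#' Write multiverse results, summary and manifest to a directory
#'
#' Writes `results.csv` (long format, stable column order, floats at 6
#' significant digits so reruns are byte-identical), `summary.json`
#' (verdict and sign percentages) and `manifest.json`.
#'
#' @param result A `multiverse_result`.
#' @param out_dir Output directory (created if absent).
#' @param manifest Manifest list; default [run_manifest()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_multiverse_results <- function(result, out_dir,
                                     manifest = run_manifest(result)) {
  stopifnot(inherits(result, "multiverse_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(results = file.path(out_dir, "results.csv"),
             summary = file.path(out_dir, "summary.json"),
             manifest = file.path(out_dir, "manifest.json"))
  tab <- tibble::as_tibble(result)[, result_column_order(result)]
  if (nrow(tab) == 0) {
    warning("empty result: writing header-only CSV", call. = FALSE)
  }
  readr::write_csv(format_numeric_cols(tab), paths[["results"]], na = "")
  summary <- if (nrow(tab) > 0) summarize_verdicts(result) else
    tibble::tibble()
  jsonlite::write_json(
    list(manifest_id = manifest$manifest_id, summary = summary),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Read back a results CSV written by [write_multiverse_results()]
#'
#' @param path Path to `results.csv`.
#' @return Tibble with the documented column types.
#' @export
read_multiverse_results <- function(path) {
  readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      universe_id = readr::col_integer(),
      is_original = readr::col_logical(),
      effect_type = readr::col_character(),
      estimand = readr::col_character(),
      estimate = readr::col_double(),
      ci_lower = readr::col_double(),
      ci_upper = readr::col_double(),
      significant = readr::col_logical(),
      causal_steps = readr::col_logical(),
      proportion_mediated = readr::col_double(),
      criteria_verdict = readr::col_logical(),
      ci_verdict = readr::col_logical(),
      n_complete_cases = readr::col_integer(),
      redundant_of = readr::col_integer(),
      warnings = readr::col_character()
    )
  )
}

#' Read a multiverse configuration file (YAML or JSON)
#'
#' The file declares column roles, covariate sets, decision points and
#' numerical parameters:
#'
#' ```yaml
#' roles:
#'   determinant: pct_weight_change
#'   mediator: fat_mass_kg
#'   outcome: bmd_mg_cm2
#'   pre_weight: lowest_weight_kg
#'   post_weight: weight_kg
#'   age: age
#' covariate_sets:
#'   full: [height_cm, age, shbg]
#'   no_hormonal: [height_cm, age]
#' parameters: {alpha: 0.05, proportion_threshold: 20, cie_threshold: 10,
#'              reliability: 0.822, n_draws: 20000, seed: 1}
#' decision_points:
#'   - name: determinant
#'     options: [continuous, increased_vs_stable, decreased_vs_stable]
#'   - name: confounder_set
#'     options: [full, no_hormonal]
#' ```
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `points` (list of [decision_point()]) and
#'   `config` (a [multiverse_config()]).
#' @export
read_multiverse_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE,
                                           simplifyDataFrame = FALSE),
                stop("unsupported config format '", ext,
                     "' (use yaml or json)", call. = FALSE))
  if (is.null(raw$roles) || is.null(raw$decision_points)) {
    stop("config must declare 'roles' and 'decision_points'", call. = FALSE)
  }
  points <- purrr::map(raw$decision_points, function(p) {
    decision_point(p$name, unlist(p$options))
  })
  params <- raw$parameters %||% list()
  covariate_sets <- purrr::map(raw$covariate_sets %||% list(), unlist)
  config <- do.call(multiverse_config, c(
    as.list(raw$roles),
    list(covariate_sets = covariate_sets),
    params
  ))
  list(points = points, config = config)
}
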