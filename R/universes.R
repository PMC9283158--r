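#' Declare a decision point
#'
#' A decision point is one data-analytical choice with a set of reasonable
#' alternative options. The first option is, by convention, the decision made
#' in the original analysis; the universe in which every decision point takes
#' its first option is flagged as the original specification.
#'
#' @param name Decision-point name (string).
#' @param options Character vector of option ids (unique, non-empty). A named
#'   vector supplies human-readable labels (`id = "label"`).
#' @return An object of class `decision_point`.
#' @examples
#' decision_point("determinant",
#'                c(continuous = "Continuous (% change)",
#'                  increased_vs_stable = "Increased vs stable weight"))
#' @export
decision_point <- function(name, options) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (is.null(names(options))) {
    ids <- as.character(options)
    labels <- ids
  } else {
    ids <- names(options)
    labels <- as.character(options)
  }
  if (length(ids) < 1) stop("decision point needs at least one option",
                            call. = FALSE)
  if (anyDuplicated(ids)) stop("option ids must be unique within '", name,
                               "'", call. = FALSE)
  structure(
    list(name = name,
         options = tibble::tibble(option_id = ids, label = labels)),
    class = "decision_point"
  )
}

#' @export
print.decision_point <- function(x, ...) {
  cat("<decision_point> ", x$name, ": ",
      paste(x$options$option_id, collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' The worked-example decision grid
#'
#' The five decision points of the weight-change / fat-mass / bone-mineral-
#' density reanalysis: determinant coding (3 options), confounder set (2),
#' confounder-selection strategy (2), age moderation (3) and
#' determinant-mediator interaction handling (3), giving
#' `3 x 2 x 2 x 3 x 3 = 108` universes. The first option of every point is the
#' original study's decision. Both mediation-verdict criteria (causal steps
#' plus proportion mediated, and the Monte Carlo CI of the indirect effect)
#' are evaluated for every universe rather than multiplying the grid.
#'
#' @return A list of [decision_point()] objects.
#' @export
lasa_decision_points <- function() {
  list(
    decision_point("determinant", c(
      continuous = "Continuous (% weight change)",
      increased_vs_stable = "Categorical: increased vs stable weight",
      decreased_vs_stable = "Categorical: decreased vs stable weight"
    )),
    decision_point("confounder_set", c(
      full = "A priori set incl. hormonal factors",
      no_hormonal = "A priori set excl. hormonal factors"
    )),
    decision_point("confounder_strategy", c(
      a_priori = "A priori adjustment",
      change_in_estimate = ">= 10% change in any path estimate"
    )),
    decision_point("age_group", c(
      all = "All ages",
      under_75 = "< 75 years (simple slopes)",
      over_75 = ">= 75 years (simple slopes)"
    )),
    decision_point("interaction", c(
      none = "No determinant-mediator interaction",
      pure = "Pure natural direct/indirect effects",
      total = "Total natural direct/indirect effects"
    ))
  )
}

#' Enumerate the multiverse grid
#'
#' Full Cartesian product of the declared decision points, in deterministic
#' lexicographic order: the first declared point varies slowest, option order
#' as declared. Universe ids are consecutive from 1; the first universe (all
#' first options) is the original specification.
#'
#' @param points List of [decision_point()] objects with unique names.
#' @return Tibble with columns `universe_id`, `is_original`, then one column
#'   per decision point holding the chosen option id.
#' @examples
#' nrow(enumerate_universes(lasa_decision_points()))  # 108
#' @export
enumerate_universes <- function(points) {
  if (length(points) < 1) stop("at least one decision point is required",
                               call. = FALSE)
  stopifnot(all(purrr::map_lgl(points, inherits, "decision_point")))
  nms <- purrr::map_chr(points, "name")
  if (anyDuplicated(nms)) {
    stop("duplicate decision point name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  opts <- purrr::map(points, function(p) p$options$option_id)
  names(opts) <- nms
  grid <- tidyr::expand_grid(!!!opts)
  firsts <- purrr::map_chr(opts, 1)
  is_original <- purrr::reduce(
    purrr::map2(grid, firsts, `==`), `&`
  )
  dplyr::bind_cols(
    tibble::tibble(universe_id = seq_len(nrow(grid)),
                   is_original = is_original),
    grid
  )
}

#' Count distinct total-effect specifications
#'
#' The total-effect model does not involve the mediator, so universes that
#' differ only in the determinant-mediator interaction option share one
#' total-effect specification. On the worked-example grid this collapses the
#' 108 universes to `3 x 2 x 2 x 3 = 36` total-effect specifications.
#'
#' @param universes Output of [enumerate_universes()].
#' @param drop Decision-point columns that do not enter the total-effect
#'   model; default `"interaction"`.
#' @return Tibble of distinct specifications with a representative
#'   `universe_id` (the smallest member id) and the member universe ids as a
#'   list column.
#' @export
total_effect_specifications <- function(universes, drop = "interaction") {
  keys <- setdiff(names(universes), c("universe_id", "is_original", drop))
  universes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      universe_id = min(.data$universe_id),
      members = list(sort(.data$universe_id)),
      is_original = any(.data$is_original),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$universe_id) |>
    dplyr::relocate("universe_id", "is_original")
}

#' Detect redundant universes
#'
#' Two universes are redundant when their resolved model specifications are
#' identical — e.g. when change-in-estimate confounder selection returns
#' exactly the a-priori covariate set, the two confounder-strategy options
#' lead to the same data situation. Redundant universes map to one canonical
#' universe (the smallest member id); the engine computes estimates once and
#' reports them for every member with a redundancy flag.
#'
#' @param universes Output of [enumerate_universes()].
#' @param resolved_specs Tibble with a `universe_id` column and any number of
#'   further columns describing the resolved specification (list columns
#'   allowed; they are canonicalised by sorting their elements).
#' @return Tibble `universe_id`, `canonical_id`, `redundant`.
#' @export
detect_redundancy <- function(universes, resolved_specs) {
  stopifnot("universe_id" %in% names(resolved_specs))
  stopifnot(setequal(universes$universe_id, resolved_specs$universe_id))
  spec_cols <- setdiff(names(resolved_specs), "universe_id")
  key <- purrr::pmap_chr(resolved_specs[spec_cols], function(...) {
    parts <- purrr::map_chr(list(...), function(v) {
      paste(sort(as.character(unlist(v))), collapse = ",")
    })
    paste(parts, collapse = "|")
  })
  tibble::tibble(universe_id = resolved_specs$universe_id, .key = key) |>
    dplyr::group_by(.data$.key) |>
    dplyr::mutate(canonical_id = min(.data$universe_id)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$universe_id) |>
    dplyr::transmute(universe_id = .data$universe_id,
                     canonical_id = .data$canonical_id,
                     redundant = .data$universe_id != .data$canonical_id)
}
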