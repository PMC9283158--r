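#' Percentage weight change between two measurements
#'
#' `100 * (current - lowest) / lowest`, the continuous determinant coding:
#' percent change between the self-reported lowest adult body weight and the
#' currently measured weight.
#'
#' @param lowest,current Weights in kg; both must be strictly positive.
#'   Vectorised; `NA`s propagate.
#' @return Numeric vector of percentages.
#' @export
percent_weight_change <- function(lowest, current) {
  bad <- (!is.na(lowest) & lowest <= 0) | (!is.na(current) & current <= 0)
  if (any(bad)) {
    stop("weights must be strictly positive (",
         sum(bad), " offending value(s))", call. = FALSE)
  }
  100 * (current - lowest) / lowest
}

#' Reliability-adjusted band behind the Edwards-Nunnally categorisation
#'
#' The pretest score is shrunk towards the sample mean by the reliability and
#' surrounded by a band of two standard errors of measurement:
#' adjusted pretest `= r (pre - mean) + mean`, half-width
#' `= 2 sd sqrt(1 - r)`.
#'
#' @param pre Pretest values (kg).
#' @param reliability Reliability coefficient (e.g. Cronbach's alpha) in
#'   (0, 1].
#' @param pre_mean,pre_sd Mean and standard deviation of the pretest measure;
#'   default computed from `pre`.
#' @return Tibble with columns `adjusted`, `band_lower`, `band_upper`.
#' @export
edwards_nunnally_bands <- function(pre, reliability = 0.822,
                                   pre_mean = mean(pre, na.rm = TRUE),
                                   pre_sd = stats::sd(pre, na.rm = TRUE)) {
  if (!is.numeric(reliability) || length(reliability) != 1 ||
      reliability <= 0 || reliability > 1) {
    stop("reliability must be a single value in (0, 1]", call. = FALSE)
  }
  if (!is.finite(pre_sd) || pre_sd <= 0) {
    stop("pre_sd must be a positive number", call. = FALSE)
  }
  adjusted <- reliability * (pre - pre_mean) + pre_mean
  half <- 2 * pre_sd * sqrt(1 - reliability)
  tibble::tibble(adjusted = adjusted,
                 band_lower = adjusted - half,
                 band_upper = adjusted + half)
}

#' Edwards-Nunnally categorisation of individual change
#'
#' Classifies each subject's change between a pretest and posttest measurement
#' as a significant increase, a significant decrease, or stable, using a
#' reliability-adjusted band around the pretest score (see
#' [edwards_nunnally_bands()]). A posttest above the band is `increased`,
#' below it `decreased`, and inside the band — boundary included — `stable`:
#' change must exceed the band to count, a conservative convention. As the
#' reliability approaches 1 the band collapses onto the pretest value and any
#' change becomes significant.
#'
#' @inheritParams edwards_nunnally_bands
#' @param post Posttest values (kg).
#' @return Factor with levels `decreased`, `stable`, `increased`; the
#'   per-subject band is attached as attribute `"bands"`.
#' @examples
#' edwards_nunnally_classify(pre = c(60, 60, 60), post = c(50, 60, 75),
#'                           pre_mean = 60, pre_sd = 8)
#' @export
edwards_nunnally_classify <- function(pre, post, reliability = 0.822,
                                      pre_mean = mean(pre, na.rm = TRUE),
                                      pre_sd = stats::sd(pre, na.rm = TRUE)) {
  bands <- edwards_nunnally_bands(pre, reliability, pre_mean, pre_sd)
  label <- dplyr::case_when(
    is.na(post) | is.na(pre) ~ NA_character_,
    post > bands$band_upper ~ "increased",
    post < bands$band_lower ~ "decreased",
    TRUE ~ "stable"
  )
  out <- factor(label, levels = c("decreased", "stable", "increased"))
  attr(out, "bands") <- bands
  out
}

#' Change-in-estimate confounder selection
#'
#' Evaluates each candidate covariate one at a time: the mediator model and
#' the outcome model are fitted with and without the candidate (on the same
#' complete-case rows), and the relative change
#' `100 * (adjusted - unadjusted) / unadjusted` is computed for the `a`, `b`
#' and `c_prime` path coefficients. A candidate whose maximum absolute change
#' across the three paths reaches the threshold (inclusive) is selected. The
#' total-effect path does not participate in selection.
#'
#' Paths whose unadjusted coefficient is numerically zero are skipped for that
#' candidate with a warning (the relative change is undefined).
#'
#' @inheritParams estimate_paths
#' @param candidates Character vector of candidate covariate columns; must be
#'   disjoint from the determinant, mediator and outcome.
#' @param base_covariates Covariates always present in the "unadjusted"
#'   models; default none.
#' @param threshold Selection threshold in percent; default 10 (a minimum of
#'   10% change selects).
#' @param tolerance Unadjusted coefficients below this magnitude are treated
#'   as zero.
#' @return An object of class `confounder_selection`: list with `selected`
#'   (character), `candidates`, `threshold` and `change_table` (tibble with
#'   per-candidate percent changes and the selection flag).
#' @export
change_in_estimate_select <- function(data, determinant, mediator, outcome,
                                      candidates,
                                      base_covariates = character(),
                                      threshold = 10, tolerance = 1e-10) {
  roles <- c(determinant, mediator, outcome)
  overlap <- intersect(candidates, roles)
  if (length(overlap)) {
    stop("candidates must be disjoint from determinant/mediator/outcome: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  check_columns(data, unique(c(roles, base_covariates, candidates)))
  one_candidate <- function(cand) {
    used <- unique(c(roles, base_covariates, cand))
    d <- data[stats::complete.cases(data[used]), used, drop = FALSE]
    unadj <- estimate_paths(d, determinant, mediator, outcome,
                            covariates_outcome = base_covariates)
    adj <- estimate_paths(d, determinant, mediator, outcome,
                          covariates_outcome = c(base_covariates, cand))
    pct <- function(label) {
      u <- path_coef(unadj, label)
      a <- path_coef(adj, label)
      if (abs(u) < tolerance) {
        warning("unadjusted ", label, " path is ~0 for candidate '", cand,
                "'; percent change undefined, path skipped", call. = FALSE)
        return(NA_real_)
      }
      100 * (a - u) / u
    }
    changes <- c(a = pct("a"), b = pct("b"), c_prime = pct("c_prime"))
    tibble::tibble(
      candidate = cand,
      pct_change_a = changes[["a"]],
      pct_change_b = changes[["b"]],
      pct_change_c_prime = changes[["c_prime"]],
      max_abs_change = if (all(is.na(changes))) NA_real_ else
        max(abs(changes), na.rm = TRUE)
    )
  }
  change_table <- purrr::map_dfr(candidates, one_candidate)
  change_table$selected <- !is.na(change_table$max_abs_change) &
    change_table$max_abs_change >= threshold
  structure(
    list(
      candidates = candidates,
      selected = change_table$candidate[change_table$selected],
      base_covariates = base_covariates,
      threshold = threshold,
      change_table = change_table
    ),
    class = "confounder_selection"
  )
}

#' @export
print.confounder_selection <- function(x, ...) {
  cat("<confounder_selection> threshold ", x$threshold, "%: ",
      length(x$selected), " of ", length(x$candidates),
      " candidate(s) selected\n", sep = "")
  print(x$change_table)
  invisible(x)
}

#' Tidy a confounder selection into its change table
#' @param x A `confounder_selection`.
#' @param ... Unused.
#' @method tidy confounder_selection
#' @export
tidy.confounder_selection <- function(x, ...) x$change_table
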