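#' Closed-form natural direct and indirect effects for linear models
#'
#' For a linear mediator model `M = mu0 + a X` (mu0 absorbing the intercept
#' and covariate terms at a fixed covariate profile) and a linear outcome
#' model with determinant coefficient `c'`, mediator coefficient `b` and
#' determinant-by-mediator coefficient `h`, the four natural effects for a
#' contrast `x0 -> x1` are
#'
#' \deqn{PNDE = (c' + h (mu0 + a x0)) (x1 - x0)}
#' \deqn{TNDE = (c' + h (mu0 + a x1)) (x1 - x0)}
#' \deqn{PNIE = (b + h x0) a (x1 - x0)}
#' \deqn{TNIE = (b + h x1) a (x1 - x0)}
#'
#' with total effect `PNDE + TNIE = TNDE + PNIE`. When `h = 0` the pure and
#' total versions coincide and the indirect effect reduces to `a b (x1 - x0)`.
#' All arguments are vectorised (used internally to evaluate effects across
#' Monte Carlo coefficient draws).
#'
#' @param a,b,c_prime,h,mu0 Model coefficients (see description).
#' @param x0,x1 Reference and comparison determinant values.
#' @return A list with numeric elements `pnde`, `tnde`, `pnie`, `tnie`,
#'   `total`.
#' @export
natural_effect_formulas <- function(a, b, c_prime, h = 0, mu0 = 0,
                                    x0 = 0, x1 = 1) {
  delta <- x1 - x0
  pnde <- (c_prime + h * (mu0 + a * x0)) * delta
  tnde <- (c_prime + h * (mu0 + a * x1)) * delta
  pnie <- (b + h * x0) * a * delta
  tnie <- (b + h * x1) * a * delta
  list(pnde = pnde, tnde = tnde, pnie = pnie, tnie = tnie,
       total = pnde + tnie)
}

#' Pure and total natural direct/indirect effects from fitted paths
#'
#' Plugs the fitted coefficients of a [estimate_paths()] or [simple_slopes()]
#' object into the linear-model closed forms. The mediator mean at the
#' reference determinant level (`mu0`) is evaluated at a covariate profile:
#' by default the mediator-model covariates are held at their analysis-sample
#' means (reference level for expanded factor dummies enters through the
#' means of the dummy columns).
#'
#' @param paths A `mediation_paths` object. If the outcome model carries no
#'   determinant-by-mediator term the interaction coefficient is taken as 0,
#'   in which case pure and total effects coincide.
#' @param x0,x1 Determinant contrast (reference and comparison values).
#'   Defaults 0 and 1: one unit of the determinant, e.g. one percentage point
#'   of weight change or a 0/1 category contrast.
#' @param covariate_profile Optional named numeric vector of mediator-model
#'   design values (names as in the fitted mediator model) overriding the
#'   stored sample means.
#' @return An object of class `natural_effects`: a tibble with columns
#'   `effect` (`pnde`, `tnde`, `pnie`, `tnie`, `total`) and `estimate`, with
#'   the contrast and profile stored as attributes.
#' @export
natural_effects <- function(paths, x0 = 0, x1 = 1, covariate_profile = NULL) {
  stopifnot(inherits(paths, "mediation_paths"))
  profile <- paths$profile
  if (!is.null(covariate_profile)) {
    unknown <- setdiff(names(covariate_profile), names(profile))
    if (length(unknown)) {
      stop("covariate_profile entries not in the mediator model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    profile[names(covariate_profile)] <- covariate_profile
  }
  profile[paths$terms$x] <- 0
  med_coef <- paths$fits$mediator$coefficients
  mu0 <- sum(med_coef[names(profile)] * profile)
  a <- path_coef(paths, "a")
  b <- path_coef(paths, "b")
  cp <- path_coef(paths, "c_prime")
  h <- if (paths$interaction) path_coef(paths, "interaction") else 0
  eff <- natural_effect_formulas(a, b, cp, h, mu0, x0, x1)
  structure(
    tibble::tibble(effect = names(eff), estimate = unlist(eff, use.names = FALSE)),
    x0 = x0, x1 = x1, mu0 = mu0, profile = profile,
    interaction = paths$interaction,
    class = c("natural_effects", class(tibble::tibble()))
  )
}

#' Check the natural-effect decomposition identities
#'
#' Verifies that `pnde + tnie` and `tnde + pnie` both equal the reported
#' total effect to within tolerance.
#'
#' @param effects A `natural_effects` object (or any tibble with columns
#'   `effect`, `estimate` covering the five effects).
#' @param tolerance Numeric tolerance, default `1e-8`.
#' @return Logical flag.
#' @export
effect_decomposition_check <- function(effects, tolerance = 1e-8) {
  get <- function(name) effects$estimate[match(name, effects$effect)]
  total <- get("total")
  scale <- max(1, abs(total))
  abs(get("pnde") + get("tnie") - total) <= tolerance * scale &&
    abs(get("tnde") + get("pnie") - total) <= tolerance * scale
}
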