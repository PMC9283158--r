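#' Ordinary least squares with coefficient covariance
#'
#' Shared fitting engine for the three mediation regressions and all moderated
#' variants. Solves the least-squares problem through base R's pivoted QR
#' decomposition and returns the coefficient vector together with its classical
#' (homoskedastic) covariance matrix, `sigma^2 (X'X)^{-1}`.
#'
#' Missing values are rejected: complete-case filtering is the caller's
#' responsibility (the multiverse engine filters per universe). Rank-deficient
#' designs raise an error naming the aliased columns rather than silently
#' dropping them.
#'
#' @param data A data frame containing the response and predictor columns, or a
#'   numeric predictor matrix (then `response` must be a numeric vector).
#' @param response Name of the response column (string) when `data` is a data
#'   frame, otherwise the numeric response vector.
#' @param terms Character vector of predictor column names (data-frame
#'   interface). Factors are expanded to treatment-coded dummies.
#' @param intercept Include an intercept column? Default `TRUE`.
#'
#' @return An object of class `linear_fit`: a list with elements `term_names`,
#'   `coefficients` (named numeric), `covariance` (symmetric matrix),
#'   `residual_variance`, `n_obs`, `dof_residual`, `r_squared`.
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' fit <- fit_ols(d, "y", "x")
#' tidy(fit)
#' @export
fit_ols <- function(data, response, terms = NULL, intercept = TRUE) {
  if (is.data.frame(data)) {
    stopifnot(is.character(response), length(response) == 1)
    if (!response %in% names(data)) {
      stop("response column '", response, "' not found", call. = FALSE)
    }
    missing_terms <- setdiff(terms, names(data))
    if (length(missing_terms)) {
      stop("predictor column(s) not found: ",
           paste(missing_terms, collapse = ", "), call. = FALSE)
    }
    y <- data[[response]]
    if (anyNA(y) || anyNA(data[terms])) {
      stop("missing values in design or response; filter complete cases ",
           "upstream", call. = FALSE)
    }
    x <- design_matrix(data, terms, intercept = intercept)
  } else {
    x <- as.matrix(data)
    y <- as.numeric(response)
    if (intercept && !any(apply(x, 2, function(col) all(col == 1)))) {
      x <- cbind(`(Intercept)` = 1, x)
    }
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  ols_fit_matrix(x, y)
}

# Expand covariate columns (factors -> treatment dummies) into a numeric
# design matrix; optionally prepend an intercept.
design_matrix <- function(data, terms, intercept = TRUE) {
  n <- nrow(data)
  if (length(terms) == 0) {
    x <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    # treatment coding for every factor, so the expansion matches an
    # intercept-bearing model; the intercept itself is added below
    x <- stats::model.matrix(~ ., data = as.data.frame(
      lapply(data[terms], function(col) {
        if (is.character(col) || is.logical(col)) factor(col) else col
      })
    ))[, -1, drop = FALSE]
    attr(x, "assign") <- NULL
  }
  if (intercept) x <- cbind(`(Intercept)` = rep(1, n), x)
  x
}

# Core matrix solver on base R's pivoted QR (lm.fit).
ols_fit_matrix <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) {
    stop("missing values in design or response; filter complete cases upstream",
         call. = FALSE)
  }
  n <- length(y)
  p <- ncol(x)
  if (nrow(x) != n) stop("nrow(x) != length(y)", call. = FALSE)
  if (n <= p) {
    stop("insufficient data: ", n, " observations for ", p, " terms",
         call. = FALSE)
  }
  fit <- stats::lm.fit(x, y)
  if (fit$rank < p) {
    aliased <- colnames(x)[fit$qr$pivot[(fit$rank + 1):p]]
    stop("collinear design: aliased term(s) ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  dof <- n - p
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / dof
  r <- qr.R(fit$qr)
  rinv <- backsolve(r, diag(p))
  xtx_inv <- tcrossprod(rinv)
  op <- order(fit$qr$pivot)
  xtx_inv <- xtx_inv[op, op, drop = FALSE]
  vcov <- sigma2 * xtx_inv
  vcov <- (vcov + t(vcov)) / 2
  coefs <- fit$coefficients
  dimnames(vcov) <- list(names(coefs), names(coefs))
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      term_names = names(coefs),
      coefficients = coefs,
      covariance = vcov,
      residual_variance = sigma2,
      n_obs = n,
      dof_residual = dof,
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_
    ),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("<linear_fit> ", x$n_obs, " obs, ", length(x$coefficients),
      " terms, residual variance ", signif(x$residual_variance, 4), "\n",
      sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a linear_fit into a per-term tibble
#'
#' @param x A `linear_fit`.
#' @param conf_level Confidence level for the t-based interval columns.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(pmax(diag(x$covariance), 0))
  stat <- ifelse(se > 0, x$coefficients / se, NA_real_)
  stat[x$coefficients == 0] <- 0
  p <- 2 * stats::pt(abs(stat), df = x$dof_residual, lower.tail = FALSE)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = x$dof_residual)
  tibble::tibble(
    term = x$term_names,
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(p),
    conf.low = unname(x$coefficients - tcrit * se),
    conf.high = unname(x$coefficients + tcrit * se)
  )
}

#' One-line model summary for a linear_fit
#' @param x A `linear_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `n_obs`, `df.residual`, `sigma`, `r.squared`.
#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    df.residual = x$dof_residual,
    sigma = sqrt(x$residual_variance),
    r.squared = x$r_squared
  )
}

#' Estimate, standard error and two-sided t test for one coefficient
#'
#' The significance flag uses a strict `p < alpha` rule, the convention used
#' throughout the multiverse engine.
#'
#' @param fit A `linear_fit`.
#' @param term Term name to summarise.
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @return A one-row tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `significant`.
#' @export
coefficient_summary <- function(fit, term, alpha = 0.05) {
  stopifnot(inherits(fit, "linear_fit"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  }
  if (!term %in% fit$term_names) {
    stop("unknown term '", term, "'; available: ",
         paste(fit$term_names, collapse = ", "), call. = FALSE)
  }
  row <- tidy(fit)[match(term, fit$term_names), ]
  dplyr::mutate(
    row[, c("term", "estimate", "std.error", "statistic", "p.value")],
    significant = .data$p.value < alpha
  )
}
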