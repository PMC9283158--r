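#' Build a specification curve from a multiverse result
#'
#' Orders the requested effect estimates ascendingly (ties broken by universe
#' id, so the ordering is deterministic and permutation-invariant), aligns
#' the decision-indicator matrix to that ordering, and locates the original
#' specification.
#'
#' @param result A `multiverse_result`.
#' @param effect_type One of `"indirect"`, `"direct"`, `"total"`.
#' @return An object of class `spec_curve`: list with `estimates` (tibble
#'   `rank`, `universe_id`, `estimate`, `ci_lower`, `ci_upper`,
#'   `significant`, `is_original`), `decisions` (long tibble `rank`,
#'   `decision`, `option`), `effect_type` and `original_index` (rank of the
#'   original specification, `NA` if absent).
#' @export
build_curve <- function(result, effect_type = c("indirect", "direct",
                                                "total")) {
  effect_type <- match.arg(effect_type)
  stopifnot(inherits(result, "multiverse_result"))
  decision_names <- attr(result, "decision_names")
  rows <- result[result$effect_type == effect_type, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows of effect type '", effect_type, "'",
                            call. = FALSE)
  dropped <- !is.na(rows$warnings) | is.na(rows$estimate)
  if (any(dropped)) {
    warning(sum(dropped), " universe(s) without an estimate omitted from the ",
            effect_type, " curve", call. = FALSE)
    rows <- rows[!dropped, , drop = FALSE]
  }
  rows <- dplyr::arrange(tibble::as_tibble(rows), .data$estimate,
                         .data$universe_id)
  rows$rank <- seq_len(nrow(rows))
  decisions <- rows |>
    dplyr::select("rank", dplyr::all_of(decision_names)) |>
    tidyr::pivot_longer(-"rank", names_to = "decision",
                        values_to = "option") |>
    dplyr::filter(!is.na(.data$option))
  original_index <- if (any(rows$is_original)) {
    rows$rank[rows$is_original][1]
  } else {
    NA_integer_
  }
  structure(
    list(
      estimates = rows[, c("rank", "universe_id", "estimate", "ci_lower",
                           "ci_upper", "significant", "is_original")],
      decisions = decisions,
      effect_type = effect_type,
      original_index = original_index
    ),
    class = "spec_curve"
  )
}

#' @export
print.spec_curve <- function(x, ...) {
  cat("<spec_curve> ", nrow(x$estimates), " ", x$effect_type,
      " effect estimates, original specification at rank ",
      x$original_index, "\n", sep = "")
  invisible(x)
}

#' Tidy a specification curve into one wide table
#'
#' Estimates joined with the decision options, one row per ranked
#' specification — convenient for CSV export and external plotting.
#'
#' @param x A `spec_curve`.
#' @param ... Unused.
#' @method tidy spec_curve
#' @export
tidy.spec_curve <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$decisions, names_from = "decision",
                             values_from = "option")
  dplyr::left_join(x$estimates, wide, by = "rank")
}

#' Two-panel specification-curve plot
#'
#' Top panel: effect estimates in ascending order with Monte Carlo CI
#' whiskers, significant estimates visually distinct and the original
#' specification enlarged. Bottom panel: the dot matrix of data-analytical
#' decisions producing each estimate, grouped by decision point, sharing the
#' x axis with the top panel.
#'
#' @param object A `spec_curve`.
#' @param ci Draw CI whiskers in the top panel? Default `TRUE`.
#' @param ... Unused.
#' @return A patchwork of two ggplots.
#' @method autoplot spec_curve
#' @export
autoplot.spec_curve <- function(object, ci = TRUE, ...) {
  est <- object$estimates
  est$significant <- factor(ifelse(est$significant, "significant",
                                   "non-significant"),
                            levels = c("significant", "non-significant"))
  top <- ggplot2::ggplot(est, ggplot2::aes(x = .data$rank,
                                           y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50")
  if (ci) {
    top <- top + ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      colour = "grey70", linewidth = 0.3
    )
  }
  top <- top +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant,
                                     size = .data$is_original)) +
    ggplot2::scale_colour_manual(
      values = c(significant = "#2166ac", `non-significant` = "#b2182b"),
      drop = FALSE, name = NULL
    ) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 3, `FALSE` = 1.2),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = paste(object$effect_type, "effect estimate"),
                  title = paste("Specification curve:", object$effect_type,
                                "effects")) +
    ggplot2::theme_minimal(base_size = 10)
  dec <- object$decisions
  dec$option_label <- paste(dec$decision, dec$option, sep = ": ")
  lvl <- dec |>
    dplyr::distinct(.data$decision, .data$option, .data$option_label) |>
    dplyr::arrange(.data$decision, .data$option)
  dec$option_label <- factor(dec$option_label, levels = rev(lvl$option_label))
  bottom <- ggplot2::ggplot(dec, ggplot2::aes(x = .data$rank,
                                              y = .data$option_label)) +
    ggplot2::geom_point(shape = 15, size = 1, colour = "grey25") +
    ggplot2::labs(x = "specification rank (ascending estimate)", y = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
  patchwork::wrap_plots(top, bottom, ncol = 1, heights = c(2, 1.4))
}

#' Render a specification curve to SVG or PNG
#'
#' @param curve A `spec_curve`.
#' @param path Output file path; the format defaults to the file extension.
#' @param format `"svg"` or `"png"`; SVG rendering is byte-deterministic for
#'   identical input.
#' @param width,height Device size in inches.
#' @param ci Passed to [autoplot.spec_curve()].
#' @return The output path, invisibly.
#' @export
render_curve <- function(curve, path, format = NULL, width = 9, height = 7,
                         ci = TRUE) {
  stopifnot(inherits(curve, "spec_curve"))
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  if (!format %in% c("svg", "png")) {
    stop("format must be 'svg' or 'png'", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    stop("output directory not writable: ", dir, call. = FALSE)
  }
  plot <- autoplot(curve, ci = ci)
  if (format == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot)
  invisible(path)
}
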