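# Tidy and plot methods for simulation results, in the broom/ggplot2 idiom.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> method: %s, %d members x %d columns\n",
              attr(x, "method"), nrow(x), ncol(x) - 2L))
  NextMethod()
}

#' Tidy an ensemble result table into long format
#'
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @return A long tibble. For FBA and deletion tables: `member_id`,
#'   `variable`, `value`. For FVA tables: `member_id`, `reaction`, `min`,
#'   `max`.
#' @export
tidy.ensemble_result <- function(x, ...) {
  tbl <- tibble::as_tibble(x)
  method <- attr(x, "method")
  if (identical(method, "fva")) {
    long <- tidyr::pivot_longer(tbl, cols = -c("member_id", "status"),
                                names_to = "key", values_to = "value")
    long$reaction <- sub("_(min|max)$", "", long$key)
    long$which <- sub("^.*_(min|max)$", "\\1", long$key)
    out <- tidyr::pivot_wider(long[, c("member_id", "reaction", "which",
                                       "value")],
                              names_from = "which", values_from = "value")
    return(out)
  }
  drop <- intersect(c("member_id", "status", "objective"), names(tbl))
  tidyr::pivot_longer(tbl, cols = -tidyr::all_of(drop),
                      names_to = "variable", values_to = "value")
}

#' Summarise an ensemble result
#'
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @return A one-row tibble with the method, member counts, and (when an
#'   `objective` column is present) the objective distribution summary.
#' @export
glance.ensemble_result <- function(x, ...) {
  out <- tibble::tibble(
    method = attr(x, "method"),
    n_members = nrow(x),
    n_infeasible = sum(x$status != "optimal"))
  if ("objective" %in% names(x)) {
    ok <- x$status == "optimal"
    out$mean_objective <- mean(x$objective[ok])
    out$sd_objective <- stats::sd(x$objective[ok])
  }
  out
}

#' Plot the distribution of a simulation output across an ensemble
#'
#' @param object An `ensemble_result`.
#' @param column Column to plot (default `"objective"`).
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_result <- function(object, column = "objective",
                                     bins = 30, ...) {
  tbl <- tibble::as_tibble(object)
  if (!column %in% names(tbl)) {
    stop("column ", dQuote(column), " not in result", call. = FALSE)
  }
  ggplot2::ggplot(tbl[tbl$status == "optimal", ],
                  ggplot2::aes(x = .data[[column]])) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = mean(tbl[[column]][tbl$status ==
                                                          "optimal"]),
                        linetype = "dashed") +
    ggplot2::labs(x = column, y = "members",
                  title = sprintf("Ensemble %s: %s across members",
                                  attr(object, "method"), column)) +
    ggplot2::theme_minimal()
}

#' Plot a feature-importance ranking
#'
#' @param object A `feature_influence`.
#' @param top_k Number of features shown (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_influence <- function(object, top_k = 15, ...) {
  top <- utils::head(object$ranking, top_k)
  top$feature_id <- factor(top$feature_id, levels = rev(top$feature_id))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$importance,
                                    y = .data$feature_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "importance", y = NULL,
                  title = "Feature influence on simulated outcome") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
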