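#' Plot training loss curves
#'
#' @param object a `goprose_fit`.
#' @param ... unused.
#' @return a ggplot of train/validation cross-entropy per epoch.
#' @method autoplot goprose_fit
#' @export
autoplot.goprose_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$dataset)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Token-level cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a perturbation score curve
#'
#' Deletion curves are drawn against the number of remaining category
#' terms (declining annotations to the left), addition curves against the
#' number of added terms.
#'
#' @param object a `perturbation_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot perturbation_curve
#' @export
autoplot.perturbation_curve <- function(object, ...) {
  xlab <- if (object$mode[1] == "deletion") {
    "Remaining category GO terms"
  } else {
    "Added GO terms"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$mean_score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "Mean average embedding score",
                  title = paste0(object$mode[1], " (", object$category[1], ")")) +
    ggplot2::theme_minimal()
}

#' Plot the score distribution of a report
#'
#' Histogram of the average embedding score, filled by the
#' high/moderate/low class; with `x = "confidence"` (and a `confidence`
#' column present) shows the confidence distribution per class instead.
#'
#' @param object a `score_report`.
#' @param x `"embedding_score"` or `"confidence"`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_score_report <- function(object, x = c("embedding_score", "confidence"),
                              bins = 20, ...) {
  x <- match.arg(x)
  if (x == "confidence") {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$confidence,
                                 fill = .data$score_class)) +
      ggplot2::geom_histogram(bins = bins, position = "identity",
                              alpha = 0.6) +
      ggplot2::labs(x = "Confidence score", y = "Entries",
                    fill = "Score class") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$embedding_score,
                                 fill = .data$score_class)) +
      ggplot2::geom_histogram(bins = bins) +
      ggplot2::labs(x = "Average embedding score", y = "Entries",
                    fill = "Score class") +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot score_report
#' @export
autoplot.score_report <- function(object, ...) {
  plot_score_report(object, ...)
}
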