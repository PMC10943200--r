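#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted summarizer
#'
#' @param x a `goprose_fit`.
#' @param ... unused.
#' @return the per-epoch loss trace as a long tibble: `epoch`, `dataset`
#'   (`train`/`validation`), `loss`.
#' @export
tidy.goprose_fit <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "dataset", values_to = "loss") |>
    dplyr::mutate(dataset = dplyr::recode(.data$dataset,
                                          train_loss = "train",
                                          val_loss = "validation"))
}

#' Summarize a fitted summarizer
#'
#' @param x a `goprose_fit`.
#' @param ... unused.
#' @return one-row tibble: epochs run, best epoch, final/best losses,
#'   parameter count, and the key training hyperparameters.
#' @export
glance.goprose_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    train_loss = x$history$train_loss[nrow(x$history)],
    best_val_loss = x$best_val_loss,
    n_params = x$backend$n_params(),
    learning_rate = x$config$learning_rate,
    batch_size = x$config$batch_size
  )
}
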