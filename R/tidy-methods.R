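#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Tidy the training trace of a diffusion model
#'
#' @param x A `tcr_diffusion` model.
#' @param ... Unused.
#' @return A tibble with `epoch` and `loss`.
#' @export
tidy.tcr_diffusion <- function(x, ...) x$losses

#' One-row summary of a diffusion model fit
#'
#' @inheritParams tidy.tcr_diffusion
#' @export
glance.tcr_diffusion <- function(x, ...) {
  tibble(
    n_params = n_params(x$net),
    timesteps = x$schedule$timesteps,
    epochs = x$epochs_trained,
    stopped_early = x$stopped_early,
    final_loss = utils::tail(x$losses$loss, 1)
  )
}

#' @export
autoplot.tcr_diffusion <- function(object, ...) {
  ggplot(object$losses, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "Epoch", y = "Mean noise-prediction MSE",
         title = "Diffusion training loss") +
    theme_minimal()
}

#' Tidy the held-out metric trace of a binding predictor
#'
#' @param x A `tcr_predictor`.
#' @param ... Unused.
#' @export
tidy.tcr_predictor <- function(x, ...) x$metrics

#' One-row summary of a binding predictor
#'
#' @inheritParams tidy.tcr_predictor
#' @export
glance.tcr_predictor <- function(x, ...) {
  tibble(
    variant = x$config$variant,
    head_layers = x$config$head_depth,
    dropout = x$config$dropout,
    trained = x$trained,
    accuracy = if (x$trained) utils::tail(x$metrics$accuracy, 1) else NA_real_,
    f1 = if (x$trained) utils::tail(x$metrics$f1, 1) else NA_real_
  )
}

#' @export
autoplot.tcr_predictor <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, c("accuracy", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$metric)) +
    geom_line() +
    labs(x = "Epoch", y = "Held-out value", colour = NULL,
         title = "Binding-predictor metrics") +
    theme_minimal()
}

#' @export
autoplot.tcr_latent_map <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$x, y = .data$y))
  if ("epitope" %in% names(object)) {
    p <- p + geom_point(aes(colour = .data$epitope), size = 1)
  } else {
    p <- p + geom_point(size = 1)
  }
  p + labs(x = "UMAP 1", y = "UMAP 2", title = "Latent TCR map") +
    theme_minimal()
}

#' @export
autoplot.tcr_pfm <- function(object, ...) {
  symbols <- setdiff(names(object), c("position", "n"))
  long <- tidyr::pivot_longer(object, dplyr::all_of(symbols),
                              names_to = "symbol", values_to = "freq")
  ggplot(long, aes(x = .data$position, y = .data$freq, fill = .data$symbol)) +
    geom_col(width = 0.9) +
    labs(x = "Position", y = "Frequency", fill = NULL,
         title = "Position frequency matrix") +
    theme_minimal()
}
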