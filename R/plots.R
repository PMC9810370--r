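# ggplot2-based plots for training histories, horizon errors, forecasts and
# influence matrices. ggplot2 is suggested, not imported.

gb_need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}

#' Plot a training history
#' @param history tibble from [train_model()] (`$history`)
#' @return a ggplot object with train and validation MAE per epoch
#' @export
plot_history <- function(history) {
  gb_need_ggplot()
  df <- rbind(
    data.frame(epoch = history$epoch, mae = history$train_mae,
               split = "train"),
    data.frame(epoch = history$epoch, mae = history$val_mae,
               split = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = mae,
                                   colour = split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "MAE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot MAE against the forecasting horizon
#' @param horizon numeric vector of per-step MAE (from [horizon_mae()] or
#'   [evaluate_model()]), or a named list of such vectors to compare models
#' @param sampling_interval seconds per step, for the x axis
#' @export
plot_horizon <- function(horizon, sampling_interval = 0.72) {
  gb_need_ggplot()
  if (!is.list(horizon)) horizon <- list(model = horizon)
  df <- do.call(rbind, lapply(names(horizon), function(nm) {
    data.frame(model = nm,
               seconds = seq_along(horizon[[nm]]) * sampling_interval,
               mae = horizon[[nm]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = seconds, y = mae,
                                   colour = model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "forecast horizon (s)", y = "MAE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one region's forecast against the truth
#' @param true,pred N x t_f matrices
#' @param region region index to display
#' @param sampling_interval seconds per step
#' @export
plot_forecast <- function(true, pred, region = 1L,
                          sampling_interval = 0.72) {
  gb_need_ggplot()
  tf <- ncol(true)
  df <- rbind(
    data.frame(seconds = seq_len(tf) * sampling_interval,
               value = true[region, ], series = "observed"),
    data.frame(seconds = seq_len(tf) * sampling_interval,
               value = pred[region, ], series = "predicted"))
  ggplot2::ggplot(df, ggplot2::aes(x = seconds, y = value,
                                   linetype = series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "signal", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of an influence matrix
#' @param object an [influence_matrix()]
#' @param ... unused
#' @export
autoplot.influence_matrix <- function(object, ...) {
  gb_need_ggplot()
  m <- object$I
  df <- data.frame(target = rep(seq_len(nrow(m)), ncol(m)),
                   source = rep(seq_len(ncol(m)), each = nrow(m)),
                   influence = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = source, y = target,
                                   fill = influence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "silenced region n'", y = "target region n") +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

utils::globalVariables(c("epoch", "mae", "split", "seconds", "model",
                         "value", "series", "source", "target", "influence"))
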