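#' Plot the training convergence record
#'
#' Loss and RMSE against iteration, with validation RMSE where recorded.
#' Uses ggplot2 when available, otherwise base graphics.
#'
#' @param model a `moment_cnn` from [train_moment_net()].
#' @return A ggplot object (invisibly `NULL` for the base-graphics fallback).
#' @export
plot_training <- function(model) {
  stopifnot(inherits(model, "moment_cnn"))
  rec <- model$record
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(rec, ggplot2::aes(x = iteration)) +
      ggplot2::geom_line(ggplot2::aes(y = rmse, colour = "training")) +
      ggplot2::geom_point(
        data = rec[!is.na(rec$val_rmse), ],
        ggplot2::aes(y = val_rmse, colour = "validation")) +
      ggplot2::labs(x = "iteration", y = "RMSE (Nm)", colour = NULL) +
      ggplot2::theme_minimal()
    return(p)
  }
  graphics::plot(rec$iteration, rec$rmse, type = "l",
                 xlab = "iteration", ylab = "RMSE (Nm)")
  ok <- !is.na(rec$val_rmse)
  graphics::points(rec$iteration[ok], rec$val_rmse[ok], col = 2, pch = 16)
  invisible(NULL)
}

#' Prediction-vs-truth agreement scatter
#'
#' Scatter of predicted against ground-truth moments with the 45-degree
#' reference line (perfect agreement).
#'
#' @param series an [eval_series()].
#' @return A ggplot object (invisibly `NULL` for the base-graphics fallback).
#' @export
plot_agreement <- function(series) {
  stopifnot(inherits(series, "eval_series"))
  df <- data.frame(truth = series$y, prediction = series$yhat)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = truth, y = prediction)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::geom_abline(slope = 1, intercept = 0,
                           colour = "red", linetype = "dashed") +
      ggplot2::labs(x = "ground-truth moment (Nm)",
                    y = "predicted moment (Nm)") +
      ggplot2::theme_minimal()
    return(p)
  }
  graphics::plot(df$truth, df$prediction, pch = 16, cex = 0.4,
                 xlab = "ground-truth moment (Nm)",
                 ylab = "predicted moment (Nm)")
  graphics::abline(0, 1, col = 2, lty = 2)
  invisible(NULL)
}
utils::globalVariables(c("iteration", "val_rmse", "truth", "prediction"))
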