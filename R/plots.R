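# ggplot2 displays for result objects.

#' Plot the cardinality trace of a strategy
#'
#' Step plot of the accumulated number of non-redundant identifiability
#' equations as observed nodes are inserted one at a time, with the
#' N_u target line.
#'
#' @param object An `obsremedy_cardinality`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot obsremedy_cardinality
#' @export
autoplot.obsremedy_cardinality <- function(object, ...) {
  df <- object$trace
  df$step <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$f)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$n_u, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$step, labels = df$node) +
    ggplot2::labs(
      x = "observed node inserted",
      y = "non-redundant identifiability equations f",
      title = "Cardinality accumulation",
      subtitle = paste0("dashed line: N_u = ", object$n_u)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the dynamic-programming progress of a remedy search
#'
#' Best cardinality reached at each stage (number of added observations),
#' with the N_u stopping threshold.
#'
#' @param object An `obsremedy_remedy`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot obsremedy_remedy
#' @export
autoplot.obsremedy_remedy <- function(object, ...) {
  df <- object$stage_trace
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$best_f)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$n_u, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$stage) +
    ggplot2::labs(
      x = "added observations (DP stage)",
      y = "best cardinality f",
      title = "Observation remedy search",
      subtitle = paste0("N_u = ", object$n_u, "; stopped at stage ",
                        object$stop_stage)
    ) +
    ggplot2::theme_minimal()
}
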