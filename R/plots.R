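#' Plot learning curves of a room-navigation experiment
#'
#' One line per agent: average epoch reward against epoch, with the
#' criterion marked.
#'
#' @param object A `cogseq_roomnav_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cogseq_roomnav_result <- function(object, ...) {
  ggplot2::ggplot(object$epochs,
                  ggplot2::aes(x = .data$epoch, y = .data$avg_reward,
                               group = .data$agent, colour = factor(.data$agent))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$config$criterion,
                        linetype = "dashed") +
    ggplot2::labs(x = "Epoch", y = "Average reward", colour = "Agent",
                  title = "Room navigation: reward per epoch") +
    ggplot2::ylim(0, 1)
}

#' Plot strategy-choice trajectories
#'
#' Per-batch strategy choices over episodes (the exploration-then-
#' exploitation pattern), faceted by batch.
#'
#' @param object A `cogseq_pbdm_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cogseq_pbdm_result <- function(object, ...) {
  ggplot2::ggplot(object$choices,
                  ggplot2::aes(x = .data$episode, y = .data$strategy)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::facet_wrap(~batch) +
    ggplot2::labs(x = "Episode", y = "Chosen strategy",
                  title = paste0("Strategy selection (",
                                 object$config$regime, ")"))
}

#' Plot per-stage error counts of an instructed-learning run
#'
#' @param object A `cogseq_instructed_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cogseq_instructed_result <- function(object, ...) {
  df <- object$stages[!is.na(object$stages$errors), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$errors)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~stage, scales = "free_x") +
    ggplot2::labs(x = "Epoch (10 trials)", y = "Errors",
                  title = "Instructed learning: errors per epoch by stage")
}

#' Plot the settling trajectory of a bridge search
#'
#' Activation of every unit in the relation engine and semantic area over
#' settling cycles, faceted by layer.
#'
#' @param object A `cogseq_bridge_result` (run with `trace = TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cogseq_bridge_result <- function(object, ...) {
  tr <- tidy(object)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$cycle, y = .data$act,
                                   group = .data$unit,
                                   colour = factor(.data$unit))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::facet_wrap(~layer) +
    ggplot2::labs(x = "Settling cycle", y = "Activation", colour = "Unit",
                  title = paste0("Constraint satisfaction: S", object$current,
                                 " to goal S", object$goal))
}
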