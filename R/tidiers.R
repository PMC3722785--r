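#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a room-navigation result
#'
#' @param x A `cogseq_roomnav_result`.
#' @param ... Unused.
#' @return The per-epoch log: agent, epoch, avg_reward, reached_criterion.
#' @export
tidy.cogseq_roomnav_result <- function(x, ...) x$epochs

#' One-row summary of a room-navigation result
#'
#' @param x A `cogseq_roomnav_result`.
#' @param ... Unused.
#' @return Tibble: n_agents, n_success, mean_epochs, criterion.
#' @export
glance.cogseq_roomnav_result <- function(x, ...) {
  tibble::tibble(n_agents = x$config$n_agents,
                 n_success = x$summary$n_success,
                 mean_epochs = x$summary$mean_epochs,
                 criterion = x$config$criterion)
}

#' Tidy a strategy-selection result
#'
#' @param x A `cogseq_pbdm_result`.
#' @param ... Unused.
#' @return The per-episode choice log.
#' @export
tidy.cogseq_pbdm_result <- function(x, ...) x$choices

#' One-row summary of a strategy-selection result
#'
#' @param x A `cogseq_pbdm_result`.
#' @param ... Unused.
#' @return Tibble: regime, n_batches, n_distinct_preferences,
#'   modal_preference, prop_on_top2 (fraction of batches stabilized on the
#'   two highest-reward strategies), prop_on_0.
#' @export
glance.cogseq_pbdm_result <- function(x, ...) {
  prefs <- x$batches$preference
  tibble::tibble(regime = x$config$regime,
                 n_batches = x$config$n_batches,
                 n_distinct_preferences = dplyr::n_distinct(prefs),
                 modal_preference = modal_choice(prefs),
                 prop_on_top2 = mean(prefs %in% c(2L, 3L)),
                 prop_on_0 = mean(prefs == 0L))
}

#' Tidy an instructed-learning result
#'
#' @param x A `cogseq_instructed_result`.
#' @param ... Unused.
#' @return The per-epoch stage table (stage, epoch, errors, trials).
#' @export
tidy.cogseq_instructed_result <- function(x, ...) x$stages

#' One-row summary of an instructed-learning result
#'
#' @param x A `cogseq_instructed_result`.
#' @param ... Unused.
#' @return Tibble: n_rules, pretrain_epochs, performance_errors,
#'   performance_accuracy.
#' @export
glance.cogseq_instructed_result <- function(x, ...) {
  tibble::tibble(n_rules = nrow(x$performance),
                 pretrain_epochs = x$pretrain_epochs,
                 performance_errors = sum(!x$performance$correct),
                 performance_accuracy = mean(x$performance$correct))
}

#' Tidy a bridge-finding result
#'
#' @param x A `cogseq_bridge_result`.
#' @param ... Unused.
#' @return The settling trace (cycle, layer, unit, act).
#' @export
tidy.cogseq_bridge_result <- function(x, ...) {
  if (is.null(x$settle$trace)) {
    stop("run find_bridge() with trace = TRUE", call. = FALSE)
  }
  x$settle$trace
}

#' One-row summary of a bridge-finding result
#'
#' @param x A `cogseq_bridge_result`.
#' @param ... Unused.
#' @return Tibble: current, goal, bridge_state, first_action, converged,
#'   cycles_run.
#' @export
glance.cogseq_bridge_result <- function(x, ...) {
  tibble::tibble(current = x$current, goal = x$goal,
                 bridge_state = x$bridge_state,
                 first_action = x$first_action,
                 converged = x$converged, cycles_run = x$cycles_run)
}
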