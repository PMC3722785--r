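#' Delta-rule dopamine critic
#'
#' The critic keeps a table of expected reward values V, one per discrete
#' state/context key, and emits a scalar dopamine signal as reward-prediction
#' error: a burst (`da > 0`) when the outcome is better than expected and a
#' dip (`da < 0`) when it is worse. Values update by the delta rule
#' `V <- V + alpha * (r - V)`, the tabular core shared by actor-critic
#' schemes. An effort-discounting variant shrinks positive bursts in
#' proportion to the effort spent earning them.
#'
#' @param alpha Critic learning rate in (0, 1], default 0.1.
#' @param kappa Effort-cost weight (>= 0) for [effort_discounted_da()],
#'   default 0.05.
#' @return A `cogseq_critic` list with an empty value table.
#' @export
critic <- function(alpha = 0.1, kappa = 0.05) {
  stopifnot(alpha > 0, alpha <= 1, kappa >= 0)
  structure(list(V = numeric(0), alpha = alpha, kappa = kappa),
            class = "cogseq_critic")
}

critic_value <- function(cr, key) {
  if (key %in% names(cr$V)) cr$V[[key]] else 0
}

#' Outcome dopamine: reward-prediction error at reward delivery
#'
#' Unregistered keys start at V = 0, so the first reward at a new context is
#' a full burst. `da` is clipped to \[-1, 1\].
#'
#' @param cr A `cogseq_critic`.
#' @param key Discrete state/context key (character scalar).
#' @param r Received reward in \[0, 1\].
#' @return List with `da` (scalar) and `critic` (updated state).
#' @export
outcome_da <- function(cr, key, r) {
  if (!is.numeric(r) || r < 0 || r > 1) {
    stop("reward must lie in [0, 1]", call. = FALSE)
  }
  v <- critic_value(cr, key)
  da <- max(-1, min(1, r - v))
  cr$V[[key]] <- v + cr$alpha * (r - v)
  list(da = da, critic = cr)
}

#' Effort-discounted dopamine burst
#'
#' Shrinks a positive burst in proportion to accumulated effort with a small
#' weighting term, floored at zero; dips pass through unchanged. This is the
#' direct dopaminergic cost-of-delay signal used by the strategy-selection
#' model.
#'
#' @param da Dopamine scalar.
#' @param effort Accumulated effort (trials, >= 0).
#' @param kappa Effort-cost weight, default 0.05.
#' @return Discounted dopamine scalar.
#' @export
effort_discounted_da <- function(da, effort, kappa = 0.05) {
  stopifnot(effort >= 0, kappa >= 0)
  if (da > 0) max(0, da - kappa * effort) else da
}

#' @export
print.cogseq_critic <- function(x, ...) {
  cat("<cogseq_critic> alpha=", x$alpha, " kappa=", x$kappa,
      " (", length(x$V), " keys)\n", sep = "")
  invisible(x)
}
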