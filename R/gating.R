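#' Basal-ganglia style gated working-memory stripes
#'
#' A stripe is an independently gatable prefrontal maintenance slot. Go and
#' NoGo matrix units receive the current input features; when the noisy
#' Go-minus-NoGo margin clears a threshold the update gate fires and new
#' content is loaded, otherwise the maintained pattern is robustly held. A
#' separate output gate releases the maintained pattern to drive responses.
#' Dopamine trains the matrix weights by a three-factor rule applied to the
#' eligibility trace of recent gating events.
#'
#' @param n_features Length of the input feature vector seen by the matrix.
#' @param slot_size Length of the maintained pattern.
#' @param theta Gate threshold on the Go-NoGo margin, default 0.
#' @param sigma Exploration noise s.d. on the margin, default 0.1.
#' @param go_w,nogo_w Optional initial weight vectors (default: uniform in
#'   \[0.25, 0.75\], drawn from the current RNG stream).
#' @return A `cogseq_stripe` list.
#' @export
stripe <- function(n_features, slot_size = n_features, theta = 0,
                   sigma = 0.1, go_w = NULL, nogo_w = NULL) {
  if (is.null(go_w)) go_w <- stats::runif(n_features, 0.25, 0.75)
  if (is.null(nogo_w)) nogo_w <- stats::runif(n_features, 0.25, 0.75)
  stopifnot(length(go_w) == n_features, length(nogo_w) == n_features)
  structure(
    list(maint = NULL, out = numeric(slot_size),
         go_w = go_w, nogo_w = nogo_w,
         theta = theta, sigma = sigma,
         slot_size = as.integer(slot_size),
         forced_nogo = FALSE, eligibility = NULL),
    class = "cogseq_stripe"
  )
}

#' Update-gate decision
#'
#' `fired` iff `go_net - nogo_net + noise > theta` and the stripe is not in
#' forced-NoGo mode (forced NoGo vetoes gating unconditionally, e.g. while a
#' task is being performed). The (features, fired) pair is recorded as the
#' eligibility trace for later dopamine credit.
#'
#' @param st A `cogseq_stripe`.
#' @param features Input feature vector.
#' @return List `decision` (`fired`, `go_net`, `nogo_net`, `noise_draw`,
#'   `margin`) and `stripe` (with eligibility recorded).
#' @export
gate <- function(st, features) {
  stopifnot(all(is.finite(features)), length(features) == length(st$go_w))
  go_net <- sum(st$go_w * features)
  nogo_net <- sum(st$nogo_w * features)
  noise <- if (st$sigma > 0) stats::rnorm(1, 0, st$sigma) else 0
  margin <- go_net - nogo_net + noise
  fired <- (margin > st$theta) && !st$forced_nogo
  decision <- list(fired = fired, go_net = go_net, nogo_net = nogo_net,
                   noise_draw = noise, margin = margin)
  st$eligibility <- list(features = features, fired = fired)
  list(decision = decision, stripe = st)
}

#' Apply an update-gate decision to maintained content
#'
#' @param st A `cogseq_stripe`.
#' @param decision A decision from [gate()].
#' @param candidate Pattern to load if the gate fired.
#' @return Updated stripe; `maint` is replaced only when the gate fired.
#' @export
update_maintenance <- function(st, decision, candidate) {
  stopifnot(length(candidate) == st$slot_size)
  if (isTRUE(decision$fired)) st$maint <- candidate
  st
}

#' Output gate: release maintained content
#'
#' @param st A `cogseq_stripe`.
#' @param out_decision A decision from [gate()] for the output gate.
#' @return The output pattern: `maint` when fired, zeros otherwise. Out-gating
#'   an empty stripe yields zeros with a warning.
#' @export
out_gate <- function(st, out_decision) {
  if (!isTRUE(out_decision$fired)) return(numeric(st$slot_size))
  if (is.null(st$maint)) {
    warning("out-gating an empty stripe; returning zeros", call. = FALSE)
    return(numeric(st$slot_size))
  }
  st$maint
}

#' Train matrix weights from dopamine
#'
#' For a gated (fired) trace: `go_w += lr * da * features`,
#' `nogo_w -= lr * da * features` — rewarded gating is repeated, punished
#' gating opposed. For a non-gated trace the signs reverse at a quarter of
#' the rate, letting options that were passed over regain credit when the
#' chosen course fails. Weights are clipped to \[0, 1\].
#'
#' @param st A `cogseq_stripe` with an eligibility trace.
#' @param da Dopamine scalar.
#' @param lr Learning rate, default 0.1.
#' @param trace Optional explicit eligibility trace (list with `features`,
#'   `fired`); defaults to the stripe's most recent one.
#' @return Updated stripe.
#' @export
learn_from_da <- function(st, da, lr = 0.1, trace = NULL) {
  tr <- if (is.null(trace)) st$eligibility else trace
  if (is.null(tr)) stop("no eligibility trace present", call. = FALSE)
  if (da != 0) {
    rate_sign <- if (isTRUE(tr$fired)) lr else -0.25 * lr
    st$go_w <- clip01(st$go_w + rate_sign * da * tr$features)
    st$nogo_w <- clip01(st$nogo_w - rate_sign * da * tr$features)
  }
  st
}

#' Competition among a set of stripes
#'
#' Each stripe takes its own update-gate decision on its own feature vector;
#' among those that fired, the one with the largest margin wins. If none
#' fires, a uniform forced-exploration pick is made (and flagged). Every
#' stripe's eligibility trace records whether it was the selected one, which
#' is the `fired` status that dopamine credit later sees.
#'
#' @param stripes List of `cogseq_stripe`.
#' @param feature_list List of feature vectors, one per stripe.
#' @return List: `winner` (index), `forced_exploration` (logical),
#'   `decisions`, and `stripes` (traces updated).
#' @export
compete_stripes <- function(stripes, feature_list) {
  stopifnot(length(stripes) == length(feature_list))
  decisions <- vector("list", length(stripes))
  for (i in seq_along(stripes)) {
    g <- gate(stripes[[i]], feature_list[[i]])
    decisions[[i]] <- g$decision
    stripes[[i]] <- g$stripe
  }
  fired <- vapply(decisions, function(d) d$fired, logical(1))
  forced <- !any(fired)
  winner <- if (forced) {
    sample.int(length(stripes), 1)
  } else {
    margins <- vapply(decisions, function(d) d$margin, numeric(1))
    margins[!fired] <- -Inf
    which.max(margins)
  }
  for (i in seq_along(stripes)) {
    stripes[[i]]$eligibility$fired <- (i == winner)
  }
  list(winner = winner, forced_exploration = forced,
       decisions = decisions, stripes = stripes)
}
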