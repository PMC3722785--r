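#' Reward/effort-based strategy selection (PBDM)
#'
#' Models the choice among four task strategies (labelled Distance,
#' Dist+BaseRate, Dist+Radius, Dist+BaseRate+Radius, i.e. strategies 0-3,
#' in increasing order of both effort and reward probability) by the
#' interaction of: orbitofrontal (OFC) stripes holding running-average reward
#' probabilities, anterior-cingulate (ACC) stripes holding running-average
#' effort, and a dorsolateral-prefrontal (DLPFC) gating circuit whose Go
#' pathway is biased by the OFC codes and whose NoGo pathway is biased by the
#' ACC codes. The inner task is abstracted to its feedback parameters: each
#' strategy costs a number of performance trials and pays a Bernoulli reward.
#'
#' Each episode runs the trial modes CHOICE (gate a strategy into DLPFC),
#' PERF x delay (forced NoGo: no mid-task switching; effort accrues), DONE
#' (reward sampled; dopamine computed, optionally effort-discounted; value
#' stripes and matrix weights updated).
#'
#' @name pbdm
NULL

#' Strategy table for a regime
#'
#' The three printed regimes: `reward_only` sets reward probabilities
#' .2/.4/.6/.8 with a constant 1-trial delay; `delay_only` sets probability
#' .6 everywhere with delays 1-4 trials (and relies on effort-discounted
#' bursts); `balanced` sets rewards .4/.6/.6/.8 against delay factors
#' .2/.4/.6/.8 (a delay factor scales a 5-trial maximum).
#'
#' @param regime One of `"reward_only"`, `"delay_only"`, `"balanced"`.
#' @return Tibble: strategy (0-3), label, reward_prob, delay_trials.
#' @export
strategy_table <- function(regime = c("reward_only", "delay_only", "balanced")) {
  regime <- match.arg(regime)
  labels <- c("Distance", "Dist+BaseRate", "Dist+Radius",
              "Dist+BaseRate+Radius")
  tab <- switch(
    regime,
    reward_only = tibble::tibble(reward_prob = c(.2, .4, .6, .8),
                                 delay_trials = rep(1L, 4)),
    delay_only = tibble::tibble(reward_prob = rep(.6, 4),
                                delay_trials = 1:4),
    balanced = tibble::tibble(reward_prob = c(.4, .6, .6, .8),
                              delay_trials = as.integer(round(c(.2, .4, .6, .8) * 5)))
  )
  tibble::tibble(strategy = 0:3, label = labels) |> dplyr::bind_cols(tab)
}

#' Coarse-coded scalar encoding
#'
#' Encodes a scalar as a Gaussian bump of activation over `n_units` units
#' whose preferred values tile `range` evenly — the distributed value code
#' the OFC/ACC layers project to the gating matrix (a scalar "decoder" layer
#' reads it back out).
#'
#' @param value Scalar within `range` (clipped with a warning otherwise).
#' @param range Length-2 numeric.
#' @param n_units Units in the code, default 7.
#' @param width Bump s.d. in bins, default 1.
#' @return Activation vector of length `n_units`.
#' @export
encode_scalar <- function(value, range = c(0, 1), n_units = 7L, width = 1) {
  if (value < range[1] || value > range[2]) {
    warning("value ", value, " outside [", range[1], ", ", range[2],
            "]; clipped", call. = FALSE)
    value <- min(range[2], max(range[1], value))
  }
  centers <- seq(range[1], range[2], length.out = n_units)
  bin <- diff(range) / (n_units - 1)
  exp(-((centers - value)^2) / (2 * (width * bin)^2))
}

#' Decode a coarse-coded bump back to a scalar
#'
#' Activation-weighted mean of the unit preferred values; exact to within a
#' bin width for bumps produced by [encode_scalar()].
#'
#' @param code Activation vector.
#' @inheritParams encode_scalar
#' @return Decoded scalar.
#' @export
decode_scalar <- function(code, range = c(0, 1)) {
  centers <- seq(range[1], range[2], length.out = length(code))
  sum(code * centers) / sum(code)
}

#' Value stripes: running averages of reward and effort
#'
#' Four OFC stripes (reward probability) and four ACC stripes (effort in
#' trials), one per strategy. Only the active strategy's stripe updates; the
#' others maintain.
#'
#' @param n_strategies Number of strategies, default 4.
#' @param alpha Running-average rate, default 0.1.
#' @param effort_range Encoding range for effort, default `c(0, 5)` (a delay
#'   factor scales a 5-trial maximum).
#' @param n_units Units per value code, default 7.
#' @return A `cogseq_value_stripes` list.
#' @export
value_stripes <- function(n_strategies = 4L, alpha = 0.1,
                          effort_range = c(0, 5), n_units = 7L) {
  structure(
    list(ofc = rep(0.5, n_strategies), acc = rep(0, n_strategies),
         alpha = alpha, effort_range = effort_range, n_units = n_units),
    class = "cogseq_value_stripes"
  )
}

#' OFC update at reward delivery (DONE trials only)
#'
#' @param vs A [value_stripes()].
#' @param strategy Active strategy id (0-based).
#' @param r Reward in \[0, 1\].
#' @param mode Current trial mode; must be `"DONE"`.
#' @return Updated stripes.
#' @export
ofc_update <- function(vs, strategy, r, mode = "DONE") {
  if (!identical(mode, "DONE")) {
    stop("OFC updates only on DONE trials (got mode '", mode, "')",
         call. = FALSE)
  }
  i <- strategy + 1L
  vs$ofc[i] <- vs$ofc[i] + vs$alpha * (r - vs$ofc[i])
  vs
}

#' ACC update: effort accrual and running average
#'
#' Each PERF trial increments the within-episode effort counter by one; at
#' DONE the active stripe's running average moves toward the episode total.
#'
#' @param vs A [value_stripes()].
#' @param strategy Active strategy id (0-based).
#' @param episode_effort Total PERF trials this episode.
#' @return Updated stripes.
#' @export
acc_update <- function(vs, strategy, episode_effort) {
  i <- strategy + 1L
  vs$acc[i] <- vs$acc[i] + vs$alpha * (episode_effort - vs$acc[i])
  vs
}

value_codes <- function(vs, strategy) {
  i <- strategy + 1L
  c(encode_scalar(min(1, max(0, vs$ofc[i])), c(0, 1), vs$n_units),
    encode_scalar(min(vs$effort_range[2], max(0, vs$acc[i])),
                  vs$effort_range, vs$n_units))
}

#' Random task-cue bit patterns
#'
#' One fixed random bit pattern per task id, representing all the sensory,
#' contextual and instructional cues of a specific task. Patterns are
#' regenerated deterministically from the seed.
#'
#' @param n_tasks Number of task contexts.
#' @param n_bits Pattern length, default 20.
#' @param density Fraction of active bits, default 0.25.
#' @param seed Seed for pattern generation.
#' @return Matrix `(n_tasks, n_bits)` of 0/1.
#' @export
task_cues <- function(n_tasks, n_bits = 20L, density = 0.25, seed = 1L) {
  n_on <- max(1L, round(n_bits * density))
  cues <- matrix(0, n_tasks, n_bits)
  set.seed(seed)
  for (t in seq_len(n_tasks)) cues[t, sample.int(n_bits, n_on)] <- 1
  cues
}

#' Choose a strategy at a CHOICE trial
#'
#' Per-strategy Go/NoGo nets are computed from the concatenation of the task
#' cue with that strategy's OFC and ACC value codes; the stripe firing with
#' the largest noisy margin wins. If none fires, a uniform forced-exploration
#' pick is made and flagged.
#'
#' @param stripes List of 4 gating stripes (one per strategy).
#' @param cue Task-cue bit vector.
#' @param vs A [value_stripes()].
#' @return List: `strategy` (0-based id), `forced_exploration`, `stripes`
#'   (eligibility traces updated), `features` (per-strategy feature list).
#' @export
choose_strategy <- function(stripes, cue, vs) {
  feats <- lapply(seq_along(stripes) - 1L, function(s) {
    f <- c(cue, value_codes(vs, s))
    f / sqrt(sum(f^2)) # unit norm: margins and noise on a common scale
  })
  comp <- compete_stripes(stripes, feats)
  list(strategy = comp$winner - 1L, forced_exploration = comp$forced_exploration,
       stripes = comp$stripes, features = feats)
}

#' Run the PBDM strategy-selection experiment
#'
#' Trains `n_batches` networks from different random initial weights. Each
#' batch runs `episodes` episodes of the CHOICE / PERF x delay / DONE loop,
#' with the task context switching every `switch_every` episodes among
#' `n_tasks` cue patterns. A batch's stabilized preference is its modal
#' choice over the final 20% of episodes.
#'
#' @param regime `"reward_only"`, `"delay_only"` or `"balanced"`; see
#'   [strategy_table()].
#' @param n_batches Number of independently initialized batches.
#' @param episodes Episodes per batch, default 500.
#' @param n_tasks Task contexts in the pretraining pool, default 20.
#' @param switch_every Episodes between task switches, default 10.
#' @param kappa Effort-cost weight for burst discounting, default 0.05
#'   (set 0 to disable).
#' @param sigma Matrix exploration noise, default 0.1.
#' @param lr Matrix learning rate, default 0.1.
#' @param alpha Critic and value-stripe rate, default 0.1.
#' @param seed Master seed; batch seeds are derived from it.
#' @param strategies Optional custom [strategy_table()]-shaped tibble.
#' @return A `cogseq_pbdm_result`: `choices` tibble (batch, episode, task,
#'   strategy, reward, effort, da), `batches` tibble (batch, seed,
#'   preference), `preference_counts` tibble, `states` (per-batch final
#'   stripes, value stripes, critic and cue patterns, for post-hoc probes
#'   such as novel-context tests), and `config`.
#' @export
run_pbdm <- function(regime = c("reward_only", "delay_only", "balanced"),
                     n_batches = 10L, episodes = 500L, n_tasks = 20L,
                     switch_every = 10L, kappa = 0.05, sigma = 0.1,
                     lr = 0.1, alpha = 0.1, seed = 1L, strategies = NULL) {
  regime <- match.arg(regime)
  strat <- if (is.null(strategies)) strategy_table(regime) else strategies
  n_strat <- nrow(strat)
  seeds <- derive_seeds(seed, n_batches)
  choice_rows <- vector("list", n_batches)
  batch_rows <- vector("list", n_batches)
  states <- vector("list", n_batches)

  for (b in seq_len(n_batches)) {
    cues <- task_cues(n_tasks, seed = seeds[b])
    set.seed(seeds[b] + 1L)
    vs <- value_stripes(n_strat, alpha = alpha)
    nf <- ncol(cues) + 2L * vs$n_units
    stripes <- lapply(seq_len(n_strat), function(i) stripe(nf, sigma = sigma))
    cr <- critic(alpha = alpha, kappa = kappa)

    rows <- vector("list", episodes)
    for (ep in seq_len(episodes)) {
      task <- ((ep - 1L) %/% switch_every) %% n_tasks + 1L
      ch <- choose_strategy(stripes, cues[task, ], vs)
      stripes <- ch$stripes
      s <- ch$strategy
      srow <- strat[strat$strategy == s, ]
      effort <- srow$delay_trials
      # PERF trials: forced NoGo on all stripes (no mid-task switching);
      # nothing else happens at this abstraction level beyond effort accrual.
      r <- as.integer(stats::runif(1) < srow$reward_prob)
      od <- outcome_da(cr, "task", r)
      cr <- od$critic
      da <- effort_discounted_da(od$da, effort, kappa)
      vs <- ofc_update(vs, s, r, mode = "DONE")
      vs <- acc_update(vs, s, effort)
      for (i in seq_len(n_strat)) {
        stripes[[i]] <- learn_from_da(stripes[[i]], da, lr = lr)
      }
      rows[[ep]] <- tibble::tibble(batch = b, episode = ep, task = task,
                                   strategy = s, reward = r,
                                   effort = effort, da = da,
                                   ofc_est = vs$ofc[s + 1L],
                                   acc_est = vs$acc[s + 1L],
                                   forced = ch$forced_exploration)
    }
    log_b <- dplyr::bind_rows(rows)
    tail_n <- max(1L, floor(episodes * 0.2))
    tail_choices <- utils::tail(log_b$strategy, tail_n)
    pref <- modal_choice(tail_choices)
    choice_rows[[b]] <- log_b
    batch_rows[[b]] <- tibble::tibble(batch = b, seed = seeds[b],
                                      preference = pref)
    states[[b]] <- list(stripes = stripes, vs = vs, critic = cr, cues = cues)
  }
  batches <- dplyr::bind_rows(batch_rows)
  counts <- batches |>
    dplyr::count(.data$preference, name = "n_batches") |>
    dplyr::rename(strategy = "preference")
  structure(
    list(choices = dplyr::bind_rows(choice_rows), batches = batches,
         preference_counts = counts, states = states,
         config = list(regime = regime, n_batches = n_batches,
                       episodes = episodes, kappa = kappa, seed = seed,
                       strategies = strat)),
    class = "cogseq_pbdm_result"
  )
}

modal_choice <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' @export
print.cogseq_pbdm_result <- function(x, ...) {
  cat("<cogseq_pbdm_result> regime=", x$config$regime, ", ",
      x$config$n_batches, " batches\n", sep = "")
  print(x$preference_counts)
  invisible(x)
}
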