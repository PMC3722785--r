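#' One-shot hippocampal instructed learning
#'
#' Models how a novel if-then rule ("if you see condition A, do action B")
#' can be followed without error after a single exposure: a slow-learning
#' cortical pathway is pretrained on action-to-premotor mappings (verbal
#' command to motor response), a fast hippocampal associator binds each
#' condition-action pair in one shot as a sparse conjunctive episode, and at
#' test the condition alone pattern-completes to the instructed action, which
#' the pretrained pathway converts to the premotor response once the
#' basal-ganglia execution gate opens. Condition, Action and Premotor layers
#' are 10-unit localist by default.
#'
#' @name instructed
NULL

#' A set of if-then rules
#'
#' @param conditions,actions Integer vectors (0-based ids in `0:(n-1)`);
#'   conditions must be unique within a set.
#' @param n Layer size (number of distinct conditions/actions), default 10.
#' @return Tibble with columns `condition`, `action`.
#' @export
rule_set <- function(conditions, actions, n = 10L) {
  stopifnot(length(conditions) == length(actions))
  if (anyDuplicated(conditions)) {
    stop("conditions must be unique within a rule set", call. = FALSE)
  }
  if (any(conditions < 0 | conditions >= n | actions < 0 | actions >= n)) {
    stop("rule ids must lie in 0:(n-1)", call. = FALSE)
  }
  tibble::tibble(condition = as.integer(conditions),
                 action = as.integer(actions))
}

#' Random rule set fixture
#'
#' @param n_rules Number of rules, default 10.
#' @param n Layer size, default 10.
#' @return A [rule_set()] tibble with unique random conditions and random
#'   (possibly repeated) actions.
#' @export
random_rule_set <- function(n_rules = 10L, n = 10L) {
  rule_set(sample.int(n, n_rules) - 1L, sample.int(n, n_rules,
                                                   replace = TRUE) - 1L, n = n)
}

onehot <- function(i, n) {
  v <- numeric(n)
  v[i + 1L] <- 1
  v
}

#' Sparse-episode store (model hippocampus)
#'
#' Episodes are sparse conjunctive codes: the concatenated condition and
#' action localist patterns are projected through a fixed random matrix into
#' a large code layer, of which the `k_hc` most driven units form the code.
#' The condition part of the input is weighted more strongly than the action
#' part, because the condition is the retrieval cue at test: recall projects
#' the condition alone and matches the resulting cue code against stored
#' codes by overlap. One-shot fast Hebbian binding attaches the instructed
#' action pattern to each stored code.
#'
#' @param n_in Localist layer size, default 10.
#' @param n_code Code layer size, default 200.
#' @param k_hc Active units per code, default 10.
#' @param cue_weight Relative weight of the condition part of the
#'   conjunction, default 6 (condition-dominant, so that a condition-only
#'   retrieval cue reliably overlaps its stored episode above the abstain
#'   threshold, with margin for corrupted cues).
#' @param abstain_threshold Minimum overlap fraction for recall, default 0.5.
#' @return A `cogseq_episode_store` list.
#' @export
episode_store <- function(n_in = 10L, n_code = 200L, k_hc = 10L,
                          cue_weight = 6, abstain_threshold = 0.5) {
  proj <- matrix(stats::rnorm(n_code * 2L * n_in), nrow = n_code)
  structure(
    list(proj = proj, n_in = as.integer(n_in), n_code = as.integer(n_code),
         k_hc = as.integer(k_hc), cue_weight = cue_weight,
         abstain_threshold = abstain_threshold,
         keys = list(), values = list(), conditions = integer(0)),
    class = "cogseq_episode_store"
  )
}

sparse_code <- function(store, cond_pat, act_pat) {
  drive <- as.numeric(store$proj %*% c(store$cue_weight * cond_pat, act_pat))
  code <- integer(store$k_hc)
  sort(order(drive, decreasing = TRUE)[seq_len(store$k_hc)])
}

#' One-shot episode encoding
#'
#' Stores the sparse conjunctive code of (condition, action) and binds it to
#' the action pattern with fast (lr = 1) Hebbian weights — realized as
#' direct key-value storage, the endpoint of one full-rate Hebbian step.
#' Re-encoding a condition with a different action overwrites the old
#' binding (newest instruction wins).
#'
#' @param store A [episode_store()].
#' @param condition,action 0-based ids.
#' @return Updated store.
#' @export
hippo_encode <- function(store, condition, action) {
  stopifnot(condition >= 0, condition < store$n_in,
            action >= 0, action < store$n_in)
  code <- sparse_code(store, onehot(condition, store$n_in),
                      onehot(action, store$n_in))
  slot <- match(condition, store$conditions)
  if (is.na(slot)) {
    slot <- length(store$keys) + 1L
    store$conditions <- c(store$conditions, as.integer(condition))
  }
  store$keys[[slot]] <- code
  store$values[[slot]] <- onehot(action, store$n_in)
  store
}

#' Cue-driven pattern completion
#'
#' Projects the condition alone to a cue code and retrieves the stored
#' episode with the largest overlap. Below the abstain threshold (or with an
#' empty store) the recall abstains.
#'
#' @param store A [episode_store()].
#' @param condition 0-based condition id.
#' @param cue_code Optional explicit cue code (e.g. a corrupted cue);
#'   overrides the condition projection.
#' @return List: `action_pattern` (or `NULL` on abstain), `action` (0-based
#'   id or `NA`), `confidence` (overlap fraction in \[0, 1\]), `abstained`.
#' @export
hippo_recall <- function(store, condition, cue_code = NULL) {
  if (length(store$keys) == 0L) {
    return(list(action_pattern = NULL, action = NA_integer_,
                confidence = 0, abstained = TRUE))
  }
  if (is.null(cue_code)) {
    cue_code <- sparse_code(store, onehot(condition, store$n_in),
                            numeric(store$n_in))
  }
  overlaps <- vapply(store$keys,
                     function(k) length(intersect(k, cue_code)) / store$k_hc,
                     numeric(1))
  best <- which.max(overlaps)
  conf <- overlaps[best]
  if (conf < store$abstain_threshold) {
    return(list(action_pattern = NULL, action = NA_integer_,
                confidence = conf, abstained = TRUE))
  }
  pat <- store$values[[best]]
  list(action_pattern = pat, action = which.max(pat) - 1L,
       confidence = conf, abstained = FALSE)
}

#' Pretrain the action-to-premotor pathway
#'
#' Error-driven (contrastive) training of a two-layer localist network on
#' the identity action-to-premotor table until winner accuracy is 10/10
#' (or the epoch budget runs out), plus a basal-ganglia execution gate
#' trained to fire on output trials.
#'
#' @param n Layer size, default 10.
#' @param lr Learning rate, default 0.04.
#' @param max_epochs Epoch budget, default 100.
#' @return List: `W` (premotor x action weights), `epochs_used`, `converged`,
#'   `exec_gate` (a [stripe()] whose Go weights favour firing on output
#'   features).
#' @export
pretrain_action_motor <- function(n = 10L, lr = 0.04, max_epochs = 100L) {
  W <- init_weights(n, n)
  converged <- FALSE
  epochs <- 0L
  for (ep in seq_len(max_epochs)) {
    epochs <- ep
    correct <- 0L
    for (j in seq_len(n)) {
      pre <- onehot(j - 1L, n)
      net <- as.numeric(W %*% pre)
      thr <- kwta_threshold(net, 1L)
      minus <- activation_fn(net - thr)
      minus_hard <- as.numeric(minus > 0.5)
      plus <- onehot(j - 1L, n)
      if (which.max(net) == j) correct <- correct + 1L
      W <- error_driven_update(pre, minus_hard, pre, plus, W, lr = lr)
    }
    if (correct == n) {
      converged <- TRUE
      break
    }
  }
  exec_gate <- stripe(2L, slot_size = n, sigma = 0,
                      go_w = c(0.9, 0.1), nogo_w = c(0.1, 0.9))
  if (!converged) {
    warning("pretraining did not reach criterion within ", max_epochs,
            " epochs", call. = FALSE)
  }
  list(W = W, epochs_used = epochs, converged = converged,
       exec_gate = exec_gate)
}

premotor_response <- function(pretrained, action_pattern, output_trial = TRUE) {
  g <- gate(pretrained$exec_gate, as.numeric(c(output_trial, !output_trial)))
  if (!g$decision$fired) return(NA_integer_)
  net <- as.numeric(pretrained$W %*% action_pattern)
  which.max(net) - 1L
}

#' Run the three-stage instructed-learning protocol
#'
#' Pretraining (action-to-premotor mapping to criterion, hippocampus and
#' instruction untouched), Instruction (each rule presented
#' `instruction_reps` times; only the episode store changes), Performance
#' (conditions only — no Action-layer input; the premotor winner is scored
#' against the rule table). Errors are reported per 10-trial epoch.
#'
#' @param rules A [rule_set()] tibble.
#' @param instruction_reps Presentations per rule during Instruction,
#'   default 4 (a single presentation already suffices for recall; the
#'   extra repetitions mirror a short practice period).
#' @param n Layer size, default 10.
#' @param trials_per_epoch Epoch size for error reporting, default 10.
#' @return A `cogseq_instructed_result`: `stages` tibble (stage, epoch,
#'   errors, trials), `performance` tibble (trial, condition, instructed,
#'   produced, correct), `pretrain_epochs`, `store`.
#' @export
run_stages <- function(rules, instruction_reps = 4L, n = 10L,
                       trials_per_epoch = 10L) {
  pre <- pretrain_action_motor(n = n)
  store <- episode_store(n_in = n)
  W_frozen <- pre$W

  # Instruction stage: one-shot encoding, repeated for faithfulness; errors
  # counted as failed recalls immediately after each presentation
  instr_rows <- list()
  trial <- 0L
  for (rep in seq_len(max(1L, instruction_reps))) {
    for (i in seq_len(nrow(rules))) {
      trial <- trial + 1L
      if (instruction_reps > 0L) {
        store <- hippo_encode(store, rules$condition[i], rules$action[i])
      }
      rec <- hippo_recall(store, rules$condition[i])
      instr_rows[[trial]] <- tibble::tibble(
        trial = trial, condition = rules$condition[i],
        error = is.na(rec$action) || rec$action != rules$action[i])
    }
    if (instruction_reps == 0L) break
  }
  instr <- dplyr::bind_rows(instr_rows)

  # Performance stage: condition input only, no Action-layer input
  perf_rows <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    rec <- hippo_recall(store, rules$condition[i])
    produced <- if (rec$abstained) {
      # no retrieval: the premotor competition resolves on noise alone
      sample.int(n, 1L) - 1L
    } else {
      premotor_response(pre, rec$action_pattern)
    }
    perf_rows[[i]] <- tibble::tibble(
      trial = i, condition = rules$condition[i],
      instructed = rules$action[i], produced = produced,
      correct = !is.na(produced) && produced == rules$action[i])
  }
  perf <- dplyr::bind_rows(perf_rows)
  stopifnot(identical(pre$W, W_frozen)) # cortical weights frozen after pretraining

  epochize <- function(df, stage) {
    df$epoch <- (seq_len(nrow(df)) - 1L) %/% trials_per_epoch + 1L
    df |>
      dplyr::group_by(.data$epoch) |>
      dplyr::summarise(errors = sum(.data$error), trials = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(stage = stage, .before = 1)
  }
  perf$error <- !perf$correct
  stages <- dplyr::bind_rows(
    tibble::tibble(stage = "Pretraining", epoch = seq_len(pre$epochs_used),
                   errors = NA_integer_, trials = n),
    epochize(instr, "Instruction"),
    epochize(perf, "Performance")
  )
  structure(
    list(stages = stages, performance = perf, instruction = instr,
         pretrain_epochs = pre$epochs_used, store = store),
    class = "cogseq_instructed_result"
  )
}

#' @export
print.cogseq_instructed_result <- function(x, ...) {
  perf_err <- sum(!x$performance$correct)
  cat("<cogseq_instructed_result> ", nrow(x$performance),
      " rules; Performance-stage errors: ", perf_err, "\n", sep = "")
  invisible(x)
}
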