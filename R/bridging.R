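#' Constraint-satisfaction discovery of bridging states
#'
#' A dual-area settling network finds the intermediate ("bridging") state
#' between a current state and a goal state two steps away, after training
#' only on adjacent state-action-state (S-A-S) triads. The semantic area
#' (StateNodes, ActionNodes) has loose inhibition and learns simple Hebbian
#' associations between co-occurring nodes, so activation can spread from
#' both the current state and the goal and converge on the state associated
#' with both. The relation engine (BeforeState, ActionBetween, AfterState)
#' has tight inhibitory competition and learns the role relations
#' (before/action/after) with an error-driven rule, so it reads the
#' settled pattern out as a single bridge state and the first action toward
#' it. The goal is a clamped input biasing both areas.
#'
#' @name bridging
NULL

#' A state-action-state transition graph
#'
#' One action unit per directed edge (each transition is a distinct atomic
#' action), matching the training regime of adjacent-only triads.
#'
#' @param triads Tibble/data.frame with columns `before`, `action`, `after`
#'   (0-based integer ids).
#' @param n_states,n_actions Layer sizes; inferred from the triads when
#'   omitted.
#' @return A `cogseq_state_graph` list.
#' @export
state_graph <- function(triads, n_states = NULL, n_actions = NULL) {
  triads <- tibble::as_tibble(triads)
  stopifnot(all(c("before", "action", "after") %in% names(triads)),
            nrow(triads) > 0)
  if (is.null(n_states)) n_states <- max(triads$before, triads$after) + 1L
  if (is.null(n_actions)) n_actions <- max(triads$action) + 1L
  if (any(triads$before >= n_states | triads$after >= n_states |
          triads$action >= n_actions)) {
    stop("triads reference states/actions outside the declared sizes",
         call. = FALSE)
  }
  structure(list(triads = triads, n_states = as.integer(n_states),
                 n_actions = as.integer(n_actions)),
            class = "cogseq_state_graph")
}

#' Default demonstration graph
#'
#' A 3-state chain S0 -a0-> S1 -a1-> S2 plus two distractor branches from
#' S0 (S0 -a2-> S3, S0 -a3-> S4), so that the start state has three legal
#' actions and the early settling phase shows all three co-active before
#' competition resolves.
#'
#' @return A [state_graph()].
#' @export
default_state_graph <- function() {
  state_graph(tibble::tibble(
    before = c(0L, 1L, 0L, 0L),
    action = c(0L, 1L, 2L, 3L),
    after = c(1L, 2L, 3L, 4L)
  ))
}

#' Build an untrained bridging network
#'
#' @param graph A [state_graph()].
#' @param sem_k StateNodes/ActionNodes winner count, default 3 (room for
#'   current + goal + bridge to co-exist).
#' @param ab_k_start Early ActionBetween winner count, default 3, tightening
#'   to 1 over `ab_ramp` cycles.
#' @param ab_ramp Ramp length in cycles, default 25.
#' @param goal_scale Net-input scale of the goal's direct bias into the
#'   relation engine's AfterState layer, default 0.15. The goal's main route
#'   of influence is the semantic area (where it is a full-strength input);
#'   a strong direct AfterState bias would let the goal unit bootstrap its
#'   own recurrent support and outcompete the intermediate state.
#' @param max_cycles,tol,step Settling parameters (see [network_spec()]).
#' @return A `cogseq_bridging_network` list wrapping a [network_spec()].
#' @export
bridging_network <- function(graph, sem_k = 3L, ab_k_start = 3L,
                             ab_ramp = 25L, goal_scale = 0.15,
                             sem_scale = 2.5, max_cycles = 100L,
                             tol = 0.005, step = 0.3) {
  ns <- graph$n_states
  na <- graph$n_actions
  sem_k <- min(sem_k, ns)
  ab_k_start <- min(ab_k_start, na)
  eye <- function(n) diag(1, n)
  layers <- list(
    layer_spec("BeforeState", ns, k = 1L, clamped = TRUE),
    layer_spec("GoalIn", ns, k = 1L, clamped = TRUE),
    layer_spec("StateNodes", ns, k = sem_k),
    layer_spec("ActionNodes", na, k = min(sem_k, na)),
    layer_spec("ActionBetween", na, k = 1L, gain = 8,
               k_start = ab_k_start, k_ramp_cycles = ab_ramp),
    layer_spec("AfterState", ns, k = 1L, gain = 8)
  )
  half <- function(n_dst, n_src) matrix(0.5, n_dst, n_src)
  projections <- list(
    # fixed input / coupling pathways
    projection_spec("BeforeState", "StateNodes", eye(ns), scale = 1),
    projection_spec("GoalIn", "StateNodes", eye(ns), scale = 1),
    projection_spec("GoalIn", "AfterState", eye(ns), scale = goal_scale),
    projection_spec("StateNodes", "AfterState", eye(ns), scale = sem_scale),
    projection_spec("ActionNodes", "ActionBetween", eye(na), scale = 0.5),
    projection_spec("ActionBetween", "ActionNodes", eye(na), scale = 0.5),
    # relation engine (error-driven)
    projection_spec("BeforeState", "ActionBetween", half(na, ns),
                    scale = 1, rule = "error_driven"),
    projection_spec("AfterState", "ActionBetween", half(na, ns),
                    scale = 1, rule = "error_driven"),
    projection_spec("ActionBetween", "AfterState", half(ns, na),
                    scale = 1, rule = "error_driven"),
    projection_spec("BeforeState", "AfterState", half(ns, ns),
                    scale = 1, rule = "error_driven"),
    # semantic area (Hebbian, weights accumulated from zero so that
    # association strength reflects co-occurrence counts)
    projection_spec("StateNodes", "StateNodes", matrix(0, ns, ns),
                    scale = sem_scale, rule = "hebbian"),
    projection_spec("StateNodes", "ActionNodes", matrix(0, na, ns),
                    scale = sem_scale, rule = "hebbian"),
    projection_spec("ActionNodes", "StateNodes", matrix(0, ns, na),
                    scale = sem_scale, rule = "hebbian")
  )
  net <- network_spec(layers, projections, max_cycles = max_cycles,
                      tol = tol, step = step)
  structure(list(net = net, graph = graph, trained = FALSE),
            class = "cogseq_bridging_network")
}

proj_index <- function(net, src, dst) {
  for (i in seq_along(net$projections)) {
    p <- net$projections[[i]]
    if (p$src == src && p$dst == dst) return(i)
  }
  stop("no projection ", src, "->", dst, call. = FALSE)
}

train_mapping_ed <- function(W, pre, target, gain = 5, lr = 0.04) {
  # one minus phase per source pattern against the multi-hot target set, so
  # fan-out relations (several valid fillers for one source) co-exist
  # instead of competing each other down
  k <- max(1L, sum(target > 0))
  net <- as.numeric(W %*% pre)
  thr <- kwta_threshold(net, k)
  minus <- activation_fn(net - thr, gain)
  error_driven_update(pre, minus, pre, target, W, lr = lr)
}

#' Train a bridging network on its graph's triads
#'
#' Relation-engine projections are trained error-driven, one clamped triad
#' at a time (before and after predict the action; before and action predict
#' the after); semantic-area projections are trained Hebbian on the
#' co-activation of each triad's nodes. Training covers every adjacent triad
#' and nothing else: bridging over a subgoal is never trained directly.
#'
#' @param bn A [bridging_network()].
#' @param epochs Passes over the relation-role mappings, default 30.
#' @param sem_epochs Passes of semantic Hebbian training, default 5:
#'   association strength stays proportional to co-occurrence counts (a
#'   state adjacent to both query states out-drives one adjacent to only
#'   one), rather than saturating into per-node normalization.
#' @param lr_ed,lr_heb Error-driven and Hebbian learning rates.
#' @return The trained network.
#' @export
train_triads <- function(bn, epochs = 30L, sem_epochs = 5L,
                         lr_ed = 0.04, lr_heb = 0.04) {
  graph <- bn$graph
  if (nrow(graph$triads) == 0L) stop("empty triad list", call. = FALSE)
  net <- bn$net
  ns <- graph$n_states
  na <- graph$n_actions
  tr <- graph$triads

  multihot <- function(ids, n) {
    v <- numeric(n)
    v[unique(ids) + 1L] <- 1
    v
  }
  # role mappings, grouped by source pattern with multi-hot target sets
  groups <- function(src_ids, dst_ids, n_src, n_dst) {
    lapply(split(dst_ids, src_ids), identity) |>
      (\(g) lapply(seq_along(g), function(i) list(
        pre = onehot(as.integer(names(g)[i]), n_src),
        target = multihot(g[[i]], n_dst))))()
  }
  maps <- list(
    list(idx = proj_index(net, "BeforeState", "ActionBetween"),
         g = groups(tr$before, tr$action, ns, na)),
    list(idx = proj_index(net, "AfterState", "ActionBetween"),
         g = groups(tr$after, tr$action, ns, na)),
    list(idx = proj_index(net, "ActionBetween", "AfterState"),
         g = groups(tr$action, tr$after, na, ns)),
    list(idx = proj_index(net, "BeforeState", "AfterState"),
         g = groups(tr$before, tr$after, ns, ns))
  )
  for (ep in seq_len(epochs)) {
    for (m in maps) {
      for (gr in m$g) {
        net$projections[[m$idx]]$W <-
          train_mapping_ed(net$projections[[m$idx]]$W, gr$pre, gr$target,
                           lr = lr_ed)
      }
    }
  }

  i_ss <- proj_index(net, "StateNodes", "StateNodes")
  i_sa <- proj_index(net, "StateNodes", "ActionNodes")
  i_as <- proj_index(net, "ActionNodes", "StateNodes")
  for (ep in seq_len(sem_epochs)) {
    for (t in seq_len(nrow(tr))) {
      a <- onehot(tr$action[t], na)
      s_pat <- multihot(c(tr$before[t], tr$after[t]), ns)
      Wss <- hebbian_update(s_pat, s_pat, net$projections[[i_ss]]$W, lr = lr_heb)
      diag(Wss) <- 0
      net$projections[[i_ss]]$W <- Wss
      net$projections[[i_sa]]$W <- hebbian_update(s_pat, a, net$projections[[i_sa]]$W, lr = lr_heb)
      net$projections[[i_as]]$W <- hebbian_update(a, s_pat, net$projections[[i_as]]$W, lr = lr_heb)
    }
  }
  # in-degree normalization: a state's pooled support from its incoming
  # actions must not grow with how many transitions happen to lead there
  i_ab2af <- proj_index(net, "ActionBetween", "AfterState")
  Wab <- net$projections[[i_ab2af]]$W
  has_edge <- vapply(seq_len(ns), function(x) any((tr$after + 1L) == x),
                     logical(1))
  rs <- rowSums(Wab)
  target <- min(rs[has_edge])
  scale_dn <- pmin(1, target / pmax(rs, 1e-6))
  net$projections[[i_ab2af]]$W <- Wab * scale_dn
  bn$net <- net
  bn$trained <- TRUE
  bn
}

#' Find the bridging state between a current state and a goal
#'
#' Clamps the current state into the relation engine's BeforeState layer and
#' the goal into the goal input layer, settles the network, and reads the
#' AfterState winner as the bridge and the ActionBetween winner as the first
#' action. The settling trace records the phase sequence (broad early
#' activation, emergence of the intermediate state, single-winner
#' convergence).
#'
#' @param bn A trained [bridging_network()].
#' @param current,goal 0-based state ids, `current != goal`.
#' @param trace Record per-cycle snapshots (default `TRUE`).
#' @return A `cogseq_bridge_result`: `bridge_state`, `first_action`
#'   (0-based ids, `NA` when unconverged), `converged`, `cycles_run`,
#'   `settle` (the full [settle()] result).
#' @export
find_bridge <- function(bn, current, goal, trace = TRUE) {
  if (!bn$trained) warning("network has not been trained", call. = FALSE)
  if (current == goal) stop("current and goal must differ", call. = FALSE)
  ns <- bn$graph$n_states
  res <- settle(bn$net,
                clamps = list(BeforeState = onehot(current, ns),
                              GoalIn = onehot(goal, ns)),
                trace = trace)
  after <- res$final_act$AfterState
  ab <- res$final_act$ActionBetween
  ok <- res$converged && max(after) > 0.5 && max(ab) > 0.5
  structure(
    list(bridge_state = if (ok) which.max(after) - 1L else NA_integer_,
         first_action = if (ok) which.max(ab) - 1L else NA_integer_,
         converged = ok, cycles_run = res$cycles_run, settle = res,
         current = current, goal = goal),
    class = "cogseq_bridge_result"
  )
}

#' Summarize the early / mid / late phases of a settling trace
#'
#' Early is the first 20% of cycles, mid the middle 20%, late the final
#' cycle; each phase reports the set of active units (activation > 0.5) per
#' layer at the last cycle of its window.
#'
#' @param result A `cogseq_bridge_result` or `cogseq_settle` with a trace.
#' @return Tibble: phase, cycle, layer, active (list of 0-based unit ids),
#'   n_active.
#' @export
settling_phases <- function(result) {
  st <- if (inherits(result, "cogseq_bridge_result")) result$settle else result
  if (is.null(st$trace)) stop("no trace recorded", call. = FALSE)
  n_cyc <- st$cycles_run
  cyc_at <- c(early = max(1L, ceiling(0.2 * n_cyc)),
              mid = max(1L, ceiling(0.5 * n_cyc)),
              late = n_cyc)
  rows <- list()
  for (ph in names(cyc_at)) {
    snap <- st$trace[st$trace$cycle == cyc_at[[ph]], ]
    by_layer <- split(snap, snap$layer)
    for (nm in names(by_layer)) {
      act_units <- by_layer[[nm]]$unit[by_layer[[nm]]$act > 0.5]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        phase = ph, cycle = cyc_at[[ph]], layer = nm,
        active = list(act_units), n_active = length(act_units))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!st$converged) out$unconverged <- TRUE
  out
}

#' @export
print.cogseq_bridge_result <- function(x, ...) {
  cat("<cogseq_bridge_result> S", x$current, " -> goal S", x$goal, ": ",
      if (x$converged) paste0("bridge S", x$bridge_state, " via action a",
                              x$first_action)
      else "did not converge (no one-subgoal bridge found)",
      " (", x$cycles_run, " cycles)\n", sep = "")
  invisible(x)
}
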