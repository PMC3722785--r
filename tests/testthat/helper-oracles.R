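# Independent oracles used across test files.

# Tabular Q-learning on a room graph: an independent check that the
# environment's optimal policy is what the network should find.
q_learning_terminal <- function(graph, episodes = 3000, lr = 0.1,
                                eps = 0.1) {
  Q <- matrix(0, graph$n_rooms, length(graph$actions),
              dimnames = list(NULL, graph$actions))
  for (e in seq_len(episodes)) {
    room <- 0L
    path <- list()
    while (!room %in% graph$terminal_rooms) {
      legal <- legal_actions(graph, room)
      a <- if (stats::runif(1) < eps) sample(legal, 1) else {
        legal[which.max(Q[room + 1L, legal])]
      }
      nxt <- step_env(graph, room, a)
      path[[length(path) + 1L]] <- c(room, match(a, graph$actions))
      room <- nxt
    }
    r <- sample_terminal_reward(graph, room)
    for (p in path) {
      Q[p[1] + 1L, p[2]] <- Q[p[1] + 1L, p[2]] + lr * (r - Q[p[1] + 1L, p[2]])
    }
  }
  room <- 0L
  while (!room %in% graph$terminal_rooms) {
    legal <- legal_actions(graph, room)
    room <- step_env(graph, room, legal[which.max(Q[room + 1L, legal])])
  }
  room
}

# Enumerate (current, goal, midpoint) query triples of a triad table where
# exactly one 2-step path connects the pair and no direct edge exists —
# breadth-first-search ground truth for the bridging oracle.
bfs_bridge_queries <- function(triads) {
  adj <- split(triads$after, triads$before)
  out <- list()
  for (u in unique(triads$before)) {
    mids_all <- adj[[as.character(u)]]
    if (is.null(mids_all)) next
    two <- list()
    for (m in mids_all) {
      for (v in adj[[as.character(m)]]) two[[length(two) + 1L]] <- c(m, v)
    }
    if (!length(two)) next
    dests <- vapply(two, `[`, numeric(1), 2)
    for (v in unique(dests)) {
      mids <- unique(vapply(two[dests == v], `[`, numeric(1), 1))
      if (length(mids) == 1L && !(v %in% mids_all) && v != u) {
        out[[length(out) + 1L]] <- c(current = u, goal = v, mid = mids)
      }
    }
  }
  out
}

triad_action <- function(triads, before, after) {
  triads$action[triads$before == before & triads$after == after][1]
}

# Run the full random-DAG bridging oracle comparison; returns counts.
bridging_oracle_suite <- function(n_dags = 50, seed = 123,
                                  max_queries_per_dag = 3) {
  set.seed(seed)
  n_ok <- 0L
  n_tot <- 0L
  n_unconv <- 0L
  for (d in seq_len(n_dags)) {
    tri <- random_dag_triads(sample(5:8, 1))
    queries <- bfs_bridge_queries(tri)
    if (!length(queries)) next
    bn <- train_triads(bridging_network(state_graph(tri)))
    for (q in queries[seq_len(min(max_queries_per_dag, length(queries)))]) {
      res <- find_bridge(bn, q[["current"]], q[["goal"]], trace = FALSE)
      if (!res$converged) {
        n_unconv <- n_unconv + 1L
        next
      }
      n_tot <- n_tot + 1L
      hit <- res$bridge_state == q[["mid"]] &&
        res$first_action == triad_action(tri, q[["current"]], q[["mid"]])
      if (hit) n_ok <- n_ok + 1L
    }
  }
  list(ok = n_ok, total = n_tot, unconverged = n_unconv)
}
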