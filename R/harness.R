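#' Experiment orchestration
#'
#' Config loading and validation, seeded RNG management, fixture generators
#' for the synthetic task environments, and a single dispatcher that runs
#' any of the four models from a validated config and serializes its results
#' (long-format CSV logs, JSON summaries).
#'
#' @name harness
NULL

#' Derive independent sub-seeds from a master seed
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` seeds (all below 2^31).
#' @export
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483000L, n)
}

known_models <- c("roomnav", "pbdm", "instructed", "bridge")

default_config <- function(model) {
  switch(model,
    roomnav = list(n_agents = 10L, max_epochs = 25L, trials_per_epoch = 75L,
                   criterion = 0.85, sigma = 0.1, lr = 0.1, alpha = 0.1),
    pbdm = list(regime = "reward_only", n_batches = 10L, episodes = 500L,
                n_tasks = 20L, switch_every = 10L, kappa = 0.05,
                sigma = 0.1, lr = 0.1, alpha = 0.1),
    instructed = list(n_rules = 10L, instruction_reps = 4L, n = 10L),
    bridge = list(current = 0L, goal = 2L, epochs = 30L)
  )
}

#' Build a validated experiment config
#'
#' Unknown keys are rejected; omitted keys take model defaults.
#'
#' @param model One of `"roomnav"`, `"pbdm"`, `"instructed"`, `"bridge"`.
#' @param ... Model-specific parameter overrides.
#' @param seed Master seed, default 1.
#' @return A `cogseq_config` list.
#' @export
experiment_config <- function(model, ..., seed = 1L) {
  if (!model %in% known_models) {
    stop("unknown model '", model, "'; expected one of ",
         paste(known_models, collapse = ", "), call. = FALSE)
  }
  defaults <- default_config(model)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop("unknown config keys for model '", model, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  params <- utils::modifyList(defaults, overrides)
  structure(list(model = model, params = params, seed = as.integer(seed)),
            class = "cogseq_config")
}

#' Read an experiment config from YAML
#'
#' Expected schema: top-level keys `model`, optional `seed`, optional
#' `params` block of model-specific overrides.
#'
#' @param path YAML file path.
#' @return A validated `cogseq_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model)) stop("config is missing 'model'", call. = FALSE)
  extra <- setdiff(names(raw), c("model", "seed", "params"))
  if (length(extra)) {
    stop("unknown top-level config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(experiment_config,
          c(list(model = raw$model), raw$params,
            list(seed = if (is.null(raw$seed)) 1L else raw$seed)))
}

#' Write an experiment config to YAML
#'
#' @param config A `cogseq_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(list(model = config$model, seed = config$seed,
                        params = config$params), path)
  invisible(path)
}

#' Run an experiment from a config
#'
#' Dispatches to the model runner and returns its result object; optionally
#' writes the long-format trial log as CSV and the summary as JSON.
#'
#' @param config A `cogseq_config` (or a path to a YAML config).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return The model's result object.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "cogseq_config"))
  p <- config$params
  res <- switch(
    config$model,
    roomnav = run_roomnav_experiment(
      n_agents = p$n_agents, max_epochs = p$max_epochs,
      trials_per_epoch = p$trials_per_epoch, criterion = p$criterion,
      seed = config$seed, sigma = p$sigma, lr = p$lr, alpha = p$alpha),
    pbdm = run_pbdm(regime = p$regime, n_batches = p$n_batches,
                    episodes = p$episodes, n_tasks = p$n_tasks,
                    switch_every = p$switch_every, kappa = p$kappa,
                    sigma = p$sigma, lr = p$lr, alpha = p$alpha,
                    seed = config$seed),
    instructed = {
      set.seed(config$seed)
      run_stages(random_rule_set(p$n_rules, p$n),
                 instruction_reps = p$instruction_reps, n = p$n)
    },
    bridge = {
      set.seed(config$seed)
      bn <- train_triads(bridging_network(default_state_graph()),
                         epochs = p$epochs)
      find_bridge(bn, p$current, p$goal)
    }
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_result(res, out_dir, config)
  }
  res
}

save_result <- function(res, out_dir, config) {
  log_tbl <- tidy(res)
  utils::write.csv(log_tbl, file.path(out_dir, paste0(config$model, "_log.csv")),
                   row.names = FALSE)
  summary_list <- c(list(model = config$model, seed = config$seed),
                    as.list(glance(res)))
  jsonlite::write_json(summary_list,
                       file.path(out_dir, paste0(config$model, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Fixture generators for the synthetic task environments
#'
#' Writes a deterministic fixture file in the documented plain-text format:
#' `"ruleset"` (2-column CSV condition,action), `"stategraph"` (edge-list
#' CSV before,action,after), `"taskcues"` (CSV of 0/1 bit patterns), or
#' `"roomgraph"` (YAML of transitions and reward probabilities).
#'
#' @param kind Fixture kind.
#' @param path Output file path.
#' @param size Fixture size (rules, states, or tasks), default 10.
#' @param seed Seed, default 1.
#' @return `path`, invisibly.
#' @export
generate_fixture <- function(kind = c("ruleset", "stategraph", "taskcues",
                                      "roomgraph"),
                             path, size = 10L, seed = 1L) {
  kind <- match.arg(kind)
  if (size < 1L) stop("invalid size", call. = FALSE)
  set.seed(seed)
  switch(kind,
    ruleset = utils::write.csv(random_rule_set(size, n = max(size, 10L)),
                               path, row.names = FALSE),
    stategraph = utils::write.csv(random_dag_triads(size), path,
                                  row.names = FALSE),
    taskcues = utils::write.csv(as.data.frame(task_cues(size, seed = seed)),
                                path, row.names = FALSE),
    roomgraph = {
      g <- room_graph()
      yaml::write_yaml(list(transitions = g$transitions,
                            terminal_rooms = g$terminal_rooms,
                            reward_prob = as.list(g$reward_prob)), path)
    })
  invisible(path)
}

#' Random DAG triads
#'
#' Generates a random forward-only transition structure over `n_states`
#' states laid out in topological order, one distinct action per edge.
#'
#' @param n_states Number of states (>= 3).
#' @param edge_prob Probability of each forward edge, default 0.4.
#' @return Triad tibble (before, action, after) suitable for [state_graph()].
#' @export
random_dag_triads <- function(n_states = 6L, edge_prob = 0.4) {
  stopifnot(n_states >= 3L)
  rows <- list()
  aid <- 0L
  for (i in 0:(n_states - 2L)) {
    for (j in (i + 1L):(n_states - 1L)) {
      if (stats::runif(1) < edge_prob) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(before = i, action = aid, after = j)
        aid <- aid + 1L
      }
    }
  }
  if (length(rows) == 0L) {
    rows[[1L]] <- tibble::tibble(before = 0L, action = 0L, after = 1L)
  }
  dplyr::bind_rows(rows)
}

#' Read a state graph from an edge-list CSV
#'
#' @param path CSV with columns before, action, after.
#' @return A [state_graph()].
#' @export
read_state_graph <- function(path) {
  state_graph(utils::read.csv(path))
}

#' Read a rule set from a 2-column CSV
#'
#' @param path CSV with columns condition, action.
#' @return A [rule_set()] tibble.
#' @export
read_rule_set <- function(path) {
  df <- utils::read.csv(path)
  rule_set(df$condition, df$action, n = max(df$condition, df$action, 9L) + 1L)
}
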