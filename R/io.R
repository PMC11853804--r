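#' Default run configuration
#'
#' The resolved defaults for every configurable block: bandit, model,
#' group, fitting, recovery and experiment settings plus the master seed.
#' [load_config()] fills missing fields from this structure.
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    bandit = list(outcome1_probs = c(0.8, 0.2, 0.2)),
    model = list(outcome1_probs = c(0.8, 0.2, 0.2), preference = 0.625,
                 gamma = 16, alpha = 1, policy_len = 2),
    group = list(n_internal = 8, aggregation = "probabilistic",
                 n_trials = 120),
    fitting = list(prior_scale = 4, n_chains = 4, n_draws = 1000,
                   warmup = 1000),
    recovery = list(alpha_grid = c(seq(0.1, 1, by = 0.1), 1.5, 2),
                    n_seeds = 3, n_trials = 500),
    experiment = list(n_internal = c(4, 8, 16, 100),
                      mean_alpha = c(0.25, 0.5, 0.75),
                      n_seeds = 1, n_trials = 500)
  )
}

validate_config <- function(config) {
  chk <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid config field `%s`: %s", field, why),
                  call. = FALSE)
  }
  chk(all(config$bandit$outcome1_probs >= 0 & config$bandit$outcome1_probs <= 1),
      "bandit.outcome1_probs", "probabilities must lie in [0, 1]")
  chk(config$model$alpha >= 0, "model.alpha", "must be non-negative")
  chk(config$model$gamma >= 0, "model.gamma", "must be non-negative")
  chk(config$model$preference > 0 && config$model$preference < 1,
      "model.preference", "must lie in (0, 1)")
  chk(config$model$policy_len >= 1, "model.policy_len", "must be >= 1")
  chk(all(config$group$n_internal >= 1), "group.n_internal", "must be >= 1")
  chk(config$group$aggregation %in% c("probabilistic", "deterministic"),
      "group.aggregation", "must be 'probabilistic' or 'deterministic'")
  chk(config$group$n_trials >= 1, "group.n_trials", "must be >= 1")
  chk(config$fitting$prior_scale > 0, "fitting.prior_scale", "must be > 0")
  chk(all(config$recovery$alpha_grid >= 0), "recovery.alpha_grid",
      "values must be non-negative")
  chk(all(config$experiment$mean_alpha >= 0), "experiment.mean_alpha",
      "values must be non-negative")
  config
}

merge_config <- function(base, override) {
  for (name in names(override)) {
    if (is.list(base[[name]]) && is.list(override[[name]]))
      base[[name]] <- merge_config(base[[name]], override[[name]])
    else base[[name]] <- override[[name]]
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration file, fills unspecified fields from
#' [default_run_config()], and validates the result; validation errors
#' name the offending field.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return validated nested list.
#' @export
load_config <- function(path = NULL) {
  config <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    config <- merge_config(config, user)
  }
  validate_config(config)
}

#' Write a run configuration to JSON
#'
#' Lossless round-trip partner of [load_config()] (full numeric precision).
#'
#' @param config nested list as returned by [load_config()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

model_to_list <- function(model) {
  list(A = model$A,
       B = lapply(seq_len(model$n_actions), function(u) model$B[, , u]),
       C = model$C, D = model$D, E = model$E,
       policy_len = model$policy_len, gamma = model$gamma,
       alpha = model$alpha)
}

model_from_list <- function(x) {
  # jsonlite may return the B slices as a list of matrices or, when all
  # slices have identical shape, as a [u, s', s] array
  if (is.array(x$B) && length(dim(x$B)) == 3L) {
    B_slices <- lapply(seq_len(dim(x$B)[1]), function(u) x$B[u, , ])
  } else {
    B_slices <- lapply(x$B, as.matrix)
  }
  n_states <- nrow(B_slices[[1]])
  B <- array(0, dim = c(n_states, n_states, length(B_slices)))
  for (u in seq_along(B_slices)) B[, , u] <- B_slices[[u]]
  generative_model(A = as.matrix(x$A), B = B, C = x$C, D = x$D, E = x$E,
                   policy_len = x$policy_len, gamma = x$gamma,
                   alpha = x$alpha)
}

#' Serialize a group trajectory
#'
#' Writes the blanket-state record as a CSV (columns
#' `trial, group_action, observation, vote_1..vote_N`, 1-based indices,
#' comma-separated, '.' decimal) plus a JSON metadata sidecar
#' (`<path>.meta.json`) holding the aggregation mode, seed, bandit
#' configuration and the internal agents' full generative models.
#'
#' @param trajectory a [group_trajectory()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- trajectory$trials
  if (!is.null(trajectory$votes) && nrow(df) > 0) {
    votes <- as.data.frame(trajectory$votes)
    names(votes) <- paste0("vote_", seq_len(ncol(votes)))
    df <- cbind(df, votes)
  } else if (!is.null(trajectory$votes)) {
    for (i in seq_len(ncol(trajectory$votes)))
      df[[paste0("vote_", i)]] <- integer(0)
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(aggregation = trajectory$aggregation,
               n_internal = trajectory$n_internal)
  if (!is.null(trajectory$seed)) meta$seed <- trajectory$seed
  if (!is.null(trajectory$bandit))
    meta$bandit <- list(outcome1_probs = trajectory$bandit$outcome1_probs)
  if (!is.null(trajectory$internal_models))
    meta$internal_models <- lapply(trajectory$internal_models, model_to_list)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized group trajectory
#'
#' Inverse of [write_trajectory()]: `read_trajectory(write_trajectory(x))`
#' reproduces all fields, including metadata.
#'
#' @param path CSV path written by [write_trajectory()].
#' @return a [group_trajectory()].
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("trial", "group_action", "observation")
  if (!all(needed %in% names(df)))
    stop(sprintf("malformed trajectory file %s: missing columns %s", path,
                 paste(setdiff(needed, names(df)), collapse = ", ")))
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0)
    stop(sprintf("malformed trajectory row(s) %s in %s",
                 paste(utils::head(bad, 5), collapse = ", "), path))
  vote_cols <- grep("^vote_", names(df), value = TRUE)
  votes <- if (length(vote_cols) > 0)
    as.matrix(df[, vote_cols, drop = FALSE]) else NULL
  if (!is.null(votes)) {
    storage.mode(votes) <- "integer"
    dimnames(votes) <- NULL
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE) else list()
  if (length(meta$bandit$outcome1_probs) == 0) meta$bandit <- NULL
  if (length(meta$internal_models) == 0) meta$internal_models <- NULL
  trials <- df[, needed]
  trials$trial <- as.integer(trials$trial)
  trials$group_action <- as.integer(trials$group_action)
  trials$observation <- as.integer(trials$observation)
  group_trajectory(
    trials = trials, votes = votes,
    aggregation = meta$aggregation %||% "probabilistic",
    n_internal = meta$n_internal %||% if (is.null(votes)) 1L else ncol(votes),
    bandit = if (is.null(meta$bandit)) NULL
             else bandit_config(meta$bandit$outcome1_probs),
    internal_models = if (is.null(meta$internal_models)) NULL
                      else lapply(meta$internal_models, model_from_list),
    seed = meta$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
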