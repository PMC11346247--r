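# Interchange formats: behavioral logs travel as CSV with a fixed column
# set; session plans serialize to JSON.

LOG_COLUMNS <- c("block", "horizon", "episode", "session_episode",
                 "trial_in_episode", "delta", "gain", "M", "s_left",
                 "s_right", "shown_first", "side_of_big", "psi0",
                 "psi_tilde", "chosen_side", "chosen_value",
                 "choice_class", "reward", "decision_time", "rt",
                 "no_decision")

#' Write a behavioral log to CSV
#'
#' @param log a `conseq_log`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "data.frame"))
  write.csv(as.data.frame(log)[, LOG_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a behavioral log from CSV
#'
#' Validates the column set and the episode/trial index structure, so
#' external logs (e.g. from an experiment) can flow through the metric
#' and fitting functions. Required columns match what [write_log()]
#' produces; extra columns are preserved.
#'
#' @param path CSV file in the package's log schema.
#' @return a `conseq_log`.
#' @export
read_log <- function(path) {
  log <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LOG_COLUMNS, names(log))
  if (length(missing_cols))
    stop("log is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  log$no_decision <- as.logical(log$no_decision)
  for (b in unique(log$block)) {
    bl <- log[log$block == b, , drop = FALSE]
    per <- bl$horizon[1] + 1L
    tab <- table(bl$episode)
    if (any(tab != per))
      stop(sprintf("block %s: every episode must have %d trials", b, per))
    if (any(bl$trial_in_episode < 1 | bl$trial_in_episode > per))
      stop(sprintf("block %s: trial_in_episode out of range", b))
  }
  class(log) <- c("conseq_log", "data.frame")
  log
}

#' Serialize a session plan to JSON
#'
#' @param plan a `session_plan`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_session_json <- function(plan, path) {
  stopifnot(inherits(plan, "session_plan"))
  cfg <- unclass(plan$config)
  cfg$block_layout <- as.data.frame(cfg$block_layout)
  jsonlite::write_json(
    list(config = cfg, blocks = plan$blocks, trials = plan$trials),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a session plan from JSON
#'
#' @param path file written by [write_session_json()].
#' @return a `session_plan`.
#' @export
read_session_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- raw$config
  g <- unlist(cfg$G_by_horizon)
  cfg <- task_config(horizon_set = cfg$horizon_set,
                     episodes_per_horizon = cfg$episodes_per_horizon,
                     block_layout = cfg$block_layout,
                     G_by_horizon = g,
                     delta_levels = cfg$delta_levels,
                     delta_max = cfg$delta_max,
                     horizon_order = cfg$horizon_order,
                     seed = cfg$seed)
  structure(list(config = cfg, blocks = as.data.frame(raw$blocks),
                 trials = as.data.frame(raw$trials)),
            class = "session_plan")
}
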