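#' Write a trial log as tab-separated text
#'
#' One row per trial, header row, UTF-8; the column schema is the one
#' produced by [simulate_agent()] (`session`, `block`, `block_in_session`,
#' `trial_in_block`, `condition`, `uncertainty`, `goal`, `trial`, `s0`,
#' `a0`, `s1`, `a1`, `s2`, `outcome_colour`, `outcome_value`, `shocks`,
#' `excluded`, optionally `subject`).
#'
#' @param trials A trial-log data frame or an `avoid_sim` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  if (inherits(trials, "avoid_sim")) trials <- trials$trials
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial log written by [write_trial_log()]
#'
#' @param path Input file path.
#' @return A trial-log data frame.
#' @export
read_trial_log <- function(path) {
  tr <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  tr$excluded <- as.logical(tr$excluded)
  tr
}

#' Read a task configuration from a YAML file
#'
#' The file mirrors [default_task_config()]: `coins` and `transitions` as
#' column lists, `p_likely`, block scheduling settings and `goal_colours`.
#' Missing keys fall back to the defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A task configuration list.
#' @export
read_task_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_task_config()
  for (nm in names(raw)) {
    val <- raw[[nm]]
    if (nm %in% c("coins", "transitions")) val <- as.data.frame(val)
    if (nm == "p_likely") val <- unlist(val)
    cfg[[nm]] <- val
  }
  cfg
}

#' Write a task configuration to a YAML file
#'
#' @param config A task configuration list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_task_config <- function(config, path) {
  out <- lapply(config, function(x) {
    if (is.data.frame(x) || !is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
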