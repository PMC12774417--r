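#' Read and write response and trial tables
#'
#' Trial-averaged response tables are CSV files with columns `neuron_id`,
#' `condition_id`, `rate` (spikes/s); trial tables additionally carry
#' `trial_index`, `spike_count` and `duration` (see
#' [generate_poisson_trials()]).
#'
#' @param x the table to write.
#' @param path file path.
#' @return `read_response_table` / `read_trial_table` return data frames;
#'   the writers return `path` invisibly.
#' @export
read_response_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "condition_id", "rate")
  if (!all(need %in% names(df)))
    stop("response table needs columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_response_table
#' @export
write_response_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_response_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "condition_id", "trial_index", "spike_count",
            "duration")
  if (!all(need %in% names(df)))
    stop("trial table needs columns: ", paste(need, collapse = ", "))
  if (any(df$spike_count < 0)) stop("spike counts must be nonnegative")
  df
}

#' @rdname read_response_table
#' @export
write_trial_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
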