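# Raster CSV I/O. On disk neuron ids are 0-based (`time_s,neuron_id`);
# in R they are 1-based, converted at this boundary.

#' Write a spike raster as CSV
#'
#' Header `time_s,neuron_id`; ids are written 0-based, times at the left
#' edge of the emitting step.
#'
#' @param raster a [spike_raster()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  df <- data.frame(time_s = raster$time_s,
                   neuron_id = raster$neuron_id - 1L)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike raster from CSV
#'
#' @param path file written by [write_raster_csv()] (0-based ids).
#' @param n_neurons number of neurons in the originating network.
#' @param dt grid step in seconds.
#' @param duration trial length in seconds (defaults to the last spike
#'   time rounded up to the grid).
#' @return A [spike_raster()].
#' @export
read_raster_csv <- function(path, n_neurons, dt, duration = NULL) {
  df <- read.csv(path)
  if (!all(c("time_s", "neuron_id") %in% names(df)))
    stop_arg("expected columns `time_s` and `neuron_id`")
  n_steps <- if (!is.null(duration)) as.integer(round(duration / dt))
             else if (nrow(df) == 0) 1L
             else as.integer(round(max(df$time_s) / dt)) + 1L
  spike_raster(df$time_s, df$neuron_id + 1L, n_neurons, dt, n_steps)
}
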