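#' @keywords internal
imnet_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "imnet_error"), call = call))
}

#' Multichannel uniformly-sampled time series
#'
#' The common signal container of the package: a numeric matrix with one
#' column per channel, a single sample rate shared by all channels, and
#' channel names. Every processing stage (kinematic filtering, inverse
#' dynamics, EMG envelope extraction, NARX evaluation) consumes and produces
#' this type.
#'
#' @param values numeric matrix or vector, `n_samples x n_channels`.
#' @param rate_hz sample rate in Hz, a single positive number.
#' @param channels character vector of channel names (defaults to
#'   `values` column names or `ch1, ch2, ...`).
#' @param start_s start time of the first sample in seconds.
#' @return an object of class `mcts`.
#' @examples
#' ts <- mcts(cbind(sin(seq(0, 1, by = 0.02))), 50, "angle")
#' n_samples(ts)
#' @export
mcts <- function(values, rate_hz, channels = NULL, start_s = 0) {
  if (is.vector(values) && is.numeric(values)) values <- matrix(values, ncol = 1)
  if (!is.matrix(values) || !is.numeric(values))
    imnet_stop("`values` must be a numeric matrix", "imnet_shape_error")
  if (nrow(values) < 1L)
    imnet_stop("time series needs at least one sample", "imnet_shape_error")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0)
    imnet_stop("`rate_hz` must be a single positive number",
               "imnet_parameter_error")
  if (is.null(channels)) {
    channels <- colnames(values)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  }
  if (length(channels) != ncol(values))
    imnet_stop("channel names do not match the number of columns",
               "imnet_shape_error")
  colnames(values) <- channels
  structure(list(values = values, rate_hz = as.numeric(rate_hz),
                 channels = as.character(channels),
                 start_s = as.numeric(start_s)),
            class = "mcts")
}

#' @rdname mcts
#' @param x an `mcts` object.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname mcts
#' @export
n_channels <- function(x) ncol(x$values)

#' @rdname mcts
#' @export
time_points <- function(x) x$start_s + (seq_len(n_samples(x)) - 1L) / x$rate_hz

#' @export
print.mcts <- function(x, ...) {
  cat(sprintf("<mcts> %d samples x %d channels @ %g Hz (%.3f s)\n",
              n_samples(x), n_channels(x), x$rate_hz,
              n_samples(x) / x$rate_hz))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a multichannel time series as delimited text
#'
#' The on-disk format is plain CSV with one extra first line
#' `# rate_hz=<value>` carrying the sample rate, then a header of channel
#' names and one row per sample. Values round-trip to at least 9 significant
#' digits. Time stamps are implicit from the rate.
#'
#' @param path file path.
#' @return `read_timeseries` returns an `mcts`; `write_timeseries` returns
#'   `path` invisibly.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path))
    imnet_stop(paste0("file not found: ", path), "imnet_io_error")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    imnet_stop(paste0(path, ": empty or truncated time-series file (line 1)"),
               "imnet_parse_error")
  m <- regmatches(lines[1L],
                  regexec("^#\\s*rate_hz\\s*=\\s*([0-9eE.+-]+)\\s*$", lines[1L]))[[1L]]
  if (length(m) != 2L)
    imnet_stop(paste0(path, ": line 1 must be '# rate_hz=<value>'"),
               "imnet_parse_error")
  rate <- suppressWarnings(as.numeric(m[2L]))
  if (!is.finite(rate) || rate <= 0)
    imnet_stop(paste0(path, ": invalid sample rate on line 1"),
               "imnet_parse_error")
  dat <- tryCatch(
    utils::read.csv(text = paste(lines[-1L], collapse = "\n"),
                    check.names = FALSE, colClasses = "numeric"),
    error = function(e)
      imnet_stop(paste0(path, ": malformed CSV body: ", conditionMessage(e)),
                 "imnet_parse_error", call = sys.call(-4)))
  if (nrow(dat) < 1L)
    imnet_stop(paste0(path, ": no data rows (line 3)"), "imnet_parse_error")
  if (anyNA(dat))
    imnet_stop(paste0(path, ": non-numeric cell near line ",
                      which(rowSums(is.na(dat)) > 0)[1L] + 2L),
               "imnet_parse_error")
  mcts(as.matrix(dat), rate, names(dat))
}

#' @rdname read_timeseries
#' @param ts an `mcts` object.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "mcts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g", ts$rate_hz), con)
  writeLines(paste(ts$channels, collapse = ","), con)
  body <- apply(ts$values, 1L, function(r)
    paste(sprintf("%.10g", r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}
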