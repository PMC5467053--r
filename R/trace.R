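#' Single-channel extracellular trace
#'
#' Container for a raw multiunit-activity (MUA) voltage series with its
#' sampling-rate metadata. Amplitudes are in arbitrary units (a.u.); no
#' physical-unit claim is made.
#'
#' @param samples Numeric vector of voltage samples (a.u.); all finite.
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param metadata Named list of free-form annotations (slice id, genotype,
#'   drug, ...).
#' @return An object of class `mua_trace`: a list with elements `samples`,
#'   `sampling_rate_hz`, `duration_s` and `metadata`.
#' @examples
#' tr <- mua_trace(rnorm(1000), 1000)
#' tr$duration_s
#' @export
mua_trace <- function(samples, sampling_rate_hz, metadata = list()) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("trace must contain at least one sample")
  if (!all(is.finite(samples))) stop("trace samples must all be finite")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a single positive number")
  }
  structure(
    list(
      samples = samples,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      duration_s = length(samples) / sampling_rate_hz,
      metadata = metadata
    ),
    class = "mua_trace"
  )
}

#' @export
print.mua_trace <- function(x, ...) {
  cat(sprintf(
    "<mua_trace> %d samples @ %g Hz (%.3f s), range [%.3g, %.3g] a.u.\n",
    length(x$samples), x$sampling_rate_hz, x$duration_s,
    min(x$samples), max(x$samples)
  ))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.mua_trace <- function(x, downsample = 10L, ...) {
  idx <- seq(1L, length(x$samples), by = max(1L, as.integer(downsample)))
  graphics::plot(
    (idx - 1L) / x$sampling_rate_hz, x$samples[idx],
    type = "l", xlab = "time (s)", ylab = "voltage (a.u.)", ...
  )
  invisible(x)
}

# Binary trace container: magic "UPTRACE1", little-endian int32 header length,
# JSON header (sampling_rate_hz, units, n_samples, metadata), then n_samples
# little-endian 32-bit floats.
TRACE_MAGIC <- "UPTRACE1"

#' Write / read a trace in the package's binary container
#'
#' The container holds an 8-byte magic string (`"UPTRACE1"`), a little-endian
#' 32-bit header length, a JSON header carrying `sampling_rate_hz`, `units`,
#' `n_samples` and free-form metadata, then the payload as little-endian
#' 32-bit floats. Precision of the payload is single; round-trips are exact
#' to float32.
#'
#' @param trace A [mua_trace()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   [mua_trace()].
#' @examples
#' f <- tempfile(fileext = ".uptrace")
#' write_trace(mua_trace(sin(1:100), 500), f)
#' read_trace(f)
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "mua_trace"))
  header <- jsonlite::toJSON(
    list(
      sampling_rate_hz = trace$sampling_rate_hz,
      units = "a.u.",
      n_samples = length(trace$samples),
      metadata = trace$metadata
    ),
    auto_unbox = TRUE, digits = NA
  )
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(TRACE_MAGIC), con)
  writeBin(as.integer(length(hraw)), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(trace$samples, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(TRACE_MAGIC)))
  if (!identical(magic, TRACE_MAGIC)) {
    stop("not a trace container (bad magic): ", path)
  }
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  samples <- readBin(con, "numeric", n = header$n_samples, size = 4L,
                     endian = "little")
  mua_trace(samples, header$sampling_rate_hz,
            metadata = as.list(header$metadata))
}

#' Write / read a trace as delimited text
#'
#' Two comma-separated columns (`time_s`, `voltage_au`) with a header row.
#' The sampling rate is recovered from the time column on read.
#'
#' @inheritParams write_trace
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trace_csv(mua_trace(rnorm(50), 100), f)
#' read_trace_csv(f)
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "mua_trace"))
  df <- data.frame(
    time_s = (seq_along(trace$samples) - 1L) / trace$sampling_rate_hz,
    voltage_au = trace$samples
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "voltage_au") %in% names(df))) {
    stop("trace CSV must have columns time_s and voltage_au")
  }
  if (nrow(df) < 2L) stop("trace CSV needs at least two samples")
  fs <- 1 / stats::median(diff(df$time_s))
  mua_trace(df$voltage_au, fs)
}
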