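# Classed error helpers so callers can distinguish failure modes.
hrv_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "hrv_error")))
}

hrv_validation_error <- function(message) hrv_abort(message, "hrv_validation_error")
hrv_format_error     <- function(message) hrv_abort(message, "hrv_format_error")
hrv_insufficient     <- function(message) hrv_abort(message, "hrv_insufficient_data")
hrv_range_error      <- function(message) hrv_abort(message, "hrv_range_error")
hrv_io_error         <- function(message) hrv_abort(message, "hrv_io_error")
hrv_ordering_error   <- function(message) hrv_abort(message, "hrv_ordering_error")
hrv_config_error     <- function(message) hrv_abort(message, "hrv_config_error")

# Tolerance for comparisons on the time axis; times are seconds, so 1 ns
# slack absorbs float jitter without ever merging distinct samples.
.time_eps <- 1e-9

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
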