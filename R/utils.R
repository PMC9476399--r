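# Internal helpers: classed error conditions and numeric clipping.

phip_error <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "phip_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

format_error      <- function(msg) phip_error("phip_format_error", msg)
consistency_error <- function(msg) phip_error("phip_consistency_error", msg)
argument_error    <- function(msg) phip_error("phip_argument_error", msg)
data_error        <- function(msg) phip_error("phip_insufficient_data_error", msg)

# clip x into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
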