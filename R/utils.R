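# Classed conditions used across the package -------------------------------

stop_invalid_input <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("stecg_invalid_input", "stecg_error"),
                      call = call))
}

stop_invalid_param <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("stecg_invalid_param", "stecg_error"),
                      call = call))
}

stop_undefined_metric <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("stecg_undefined_metric", "stecg_error"),
                      call = call))
}

# Raised when a plane does not carry enough extrema to build both envelope
# surfaces; bemd_decompose() catches it to terminate the sifting recursion.
stop_insufficient_extrema <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c("stecg_insufficient_extrema", "stecg_error"),
                      call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_plane <- function(plane, min_dim = 1L, arg = "plane") {
  if (!is.matrix(plane) || !is.numeric(plane))
    stop_invalid_input(sprintf("`%s` must be a numeric matrix", arg))
  if (!all(is.finite(plane)))
    stop_invalid_input(sprintf("`%s` contains non-finite values", arg))
  if (nrow(plane) < min_dim || ncol(plane) < min_dim)
    stop_invalid_input(sprintf("`%s` must be at least %d x %d", arg,
                               min_dim, min_dim))
  invisible(plane)
}
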