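# Classed conditions so callers (verify_point, the CLI) can react to specific
# failure modes instead of matching message strings.

bc_stop <- function(class, msg, ..., call = sys.call(-1)) {
  data <- list(...)
  cond <- structure(
    class = c(class, "brachycheck_error", "error", "condition"),
    c(list(message = msg, call = call), data)
  )
  stop(cond)
}

bc_domain_error  <- function(msg, ...) bc_stop("brachycheck_domain_error", msg, ...)
bc_config_error  <- function(msg, ...) bc_stop("brachycheck_config_error", msg, ...)
bc_format_error  <- function(msg, ...) bc_stop("brachycheck_format_error", msg, ...)
bc_numeric_error <- function(msg, ...) bc_stop("brachycheck_numeric_error", msg, ...)

# Near-source failures carry enough context (dwell index, distance) for the
# verification layer to turn them into a diagnosed FAIL rather than an abort.
bc_near_source_error <- function(msg, ...) bc_stop("brachycheck_near_source_error", msg, ...)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    bc_domain_error(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
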