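# classed conditions -----------------------------------------------------

#' @keywords internal
abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "exofatigue_domain_error", ...)
}

#' @keywords internal
abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "exofatigue_schema_error", ...)
}

#' @keywords internal
abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "exofatigue_config_error", ...)
}

#' @keywords internal
warn_clamp <- function(msg) {
  rlang::warn(msg, class = "exofatigue_clamp_warning")
}

# scalar validators used throughout the package
check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort_domain(sprintf("`%s` must be finite and non-negative.", name))
  }
  invisible(x)
}

check_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort_domain(sprintf("`%s` must be finite and positive.", name))
  }
  invisible(x)
}
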