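# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish configuration, file-format and model-compatibility failures.

harf_error <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "harf_error")))
}

harf_config_error <- function(message, ...) {
  harf_error(message, "harf_config_error", ...)
}

harf_format_error <- function(message, ...) {
  harf_error(message, "harf_format_error", ...)
}

harf_compat_error <- function(message, ...) {
  harf_error(message, "harf_compat_error", ...)
}

harf_validation_error <- function(message, ...) {
  harf_error(message, "harf_validation_error", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
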