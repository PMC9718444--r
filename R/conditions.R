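# Classed conditions so callers (and the pipeline) can distinguish
# configuration, data and numeric failures programmatically.

cs_error <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "cs_error")))
}

stop_domain <- function(message, ...) cs_error(message, "cs_domain_error", ...)
stop_schema <- function(message, ...) cs_error(message, "cs_schema_error", ...)
stop_integrity <- function(message, ...) cs_error(message, "cs_integrity_error", ...)
stop_io <- function(message, ...) cs_error(message, "cs_io_error", ...)
stop_shape <- function(message, ...) cs_error(message, "cs_shape_error", ...)
stop_numeric <- function(message, ...) cs_error(message, "cs_numeric_error", ...)
stop_empty_stratum <- function(message, ...) cs_error(message, "cs_empty_stratum_error", ...)
stop_config <- function(message, ...) cs_error(message, "cs_config_error", ...)
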