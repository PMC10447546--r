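# Condition helpers. Every error raised by the package carries a subclass so
# callers (and tests) can distinguish invalid parameters from runtime
# failures such as a detector finding fewer than two eyes.

stop_invalid <- function(msg, ...) {
  rlang::abort(msg, class = "iriscal_invalid_parameter", ...)
}

stop_validation <- function(msg, ...) {
  rlang::abort(msg, class = "iriscal_validation_error", ...)
}

stop_detection <- function(msg, ...) {
  rlang::abort(msg, class = "iriscal_detection_failure", ...)
}

stop_segmentation <- function(msg, ...) {
  rlang::abort(msg, class = "iriscal_segmentation_failure", ...)
}

stop_undefined_metric <- function(msg, ...) {
  rlang::abort(msg, class = "iriscal_undefined_metric", ...)
}

stop_io <- function(msg, ...) {
  rlang::abort(msg, class = "iriscal_io_error", ...)
}
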