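# Classed error conditions so callers and tests can discriminate failure
# modes without string matching.

abort_icga <- function(msg, class, call = sys.call(-1), ...) {
  stop(errorCondition(msg, ..., class = c(class, "icgaOtsu_error"),
                      call = call))
}

#' @noRd
abort_degenerate_input <- function(msg, ...) {
  abort_icga(msg, "icgaOtsu_degenerate_input", ...)
}

#' @noRd
abort_degenerate_split <- function(msg, ...) {
  abort_icga(msg, "icgaOtsu_degenerate_split", ...)
}

#' @noRd
abort_constant_image <- function(msg, level = NA_integer_, ...) {
  abort_icga(msg, "icgaOtsu_constant_image", level = level, ...)
}
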