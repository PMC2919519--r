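#' @keywords internal
"_PACKAGE"

# Typed conditions: undefined correlations and bad parameters must never
# surface as silent NaN/NA. All errors share class "quantcorr_error" so
# callers can distinguish package conditions from everything else.

stop_quantcorr <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "quantcorr_error"),
                      call = call))
}

stop_undefined_correlation <- function(msg) {
  stop_quantcorr(msg, "quantcorr_undefined_correlation")
}

stop_parameter <- function(msg) {
  stop_quantcorr(msg, "quantcorr_parameter_error")
}

stop_data <- function(msg) {
  stop_quantcorr(msg, "quantcorr_data_error")
}

stop_internal <- function(msg) {
  stop_quantcorr(msg, "quantcorr_internal_error")
}
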