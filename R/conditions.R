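#' @title Classed error conditions
#' @description Internal helpers that raise classed conditions so callers and
#'   tests can distinguish validation, I/O, format and undefined-metric
#'   failures. All classes are prefixed \code{pvla}.
#' @name pvla-conditions
#' @keywords internal
NULL

pvlaStop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "pvlaError")))
}

stopValidation   <- function(msg, ...) pvlaStop(msg, "pvlaValidationError", ...)
stopIO           <- function(msg, ...) pvlaStop(msg, "pvlaIOError", ...)
stopFormat       <- function(msg, ...) pvlaStop(msg, "pvlaFormatError", ...)
stopSchema       <- function(msg, ...) pvlaStop(msg, "pvlaSchemaError", ...)
stopPrecondition <- function(msg, ...) pvlaStop(msg, "pvlaPreconditionError", ...)
stopConfig       <- function(msg, ...) pvlaStop(msg, "pvlaConfigError", ...)

## metric undefined for this input (e.g. both masks empty: Dice = 0/0)
stopUndefinedMetric <- function(msg, ...) pvlaStop(msg, "pvlaUndefinedMetricError", ...)

## index undefined: no slice carries both PV and LA
stopNoSharedSlice <- function(msg, ...) pvlaStop(msg, "pvlaNoSharedSliceError", ...)

## every shared slice is angle-degenerate
stopNoMeasurableAngle <- function(msg, ...) pvlaStop(msg, "pvlaNoMeasurableAngleError", ...)
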