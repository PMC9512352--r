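# Classed error conditions used across the package.  Every user-facing error
# carries class c("isodvh_error_<kind>", "isodvh_error", "error", "condition")
# so callers (and the CLI) can dispatch on the kind.

abort_isodvh <- function(msg, kind, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c(paste0("isodvh_error_", kind), "isodvh_error"),
                      call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Report rounding: half away from zero, as printed clinical tables round
# (base round() ties to even, which turns 43.75 into 43.7).  The tie-break
# tolerates double-precision error: a value within ~1e-8 of the .5 boundary
# (e.g. 43.749999999999996 for an exact 43.75) still rounds up.
round_report <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + sqrt(.Machine$double.eps)) / s
}
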