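# Classed conditions so callers can distinguish failure modes programmatically.
# Every error carries class c(<specific>, "halocat_error"); warnings likewise.

halocat_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "halocat_error")))
}

halocat_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "halocat_warning")))
}

# summary.lm warns on residual-free designs; exact calibration points and
# noiseless simulated curves are legitimate inputs here, so muffle just that.
quiet_lm_summary <- function(fit) {
  withCallingHandlers(summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

stopifnot_number <- function(x, name, lower = -Inf, upper = Inf,
                             allow_equal = c(TRUE, TRUE)) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    halocat_error(sprintf("`%s` must be a single finite number", name),
                  "halocat_invalid_parameter")
  lo_ok <- if (allow_equal[1]) x >= lower else x > lower
  hi_ok <- if (allow_equal[2]) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    halocat_error(sprintf("`%s` = %g is outside its allowed range", name, x),
                  "halocat_invalid_parameter")
  invisible(x)
}
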