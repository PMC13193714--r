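# internal helpers shared across modules

# Half-up rounding: the reported behavioral percentages use commercial
# rounding (62 from 61.67), not banker's rounding.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop_field(field, sprintf("must lie in %s%s, %s%s",
                              if (allow_equal_lower) "[" else "(", lower,
                              upper, if (allow_equal_upper) "]" else ")"))
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

# Derive a reproducible child seed from a base seed and a stream index,
# kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               .Machine$integer.max)
}
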