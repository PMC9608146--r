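# Shared numeric helpers.

# Half-away-from-zero rounding; all image quantities here are non-negative,
# so floor(x + 0.5) implements it exactly (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
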