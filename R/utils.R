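# internal helpers shared across modules

# Natural (numeric-aware) sort key: digit runs are zero-padded so that
# "F2" orders before "F10" (plain lexicographic order would reverse them).
naturalKey <- function(x) {
  vapply(as.character(x), function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    isnum <- grepl("^[0-9]+$", parts)
    parts[isnum] <- sprintf("%020.0f", as.numeric(parts[isnum]))
    paste(parts, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

naturalOrder <- function(x) order(naturalKey(x), x)

naturalSort <- function(x) x[naturalOrder(x)]

# Half-up decimal rounding, fixed across platforms (base round() is
# banker's). The epsilon guards against 0.4999... binary representations
# of exact decimal halves.
roundHalfUp <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
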