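# Internal helpers shared across modules.

# Deterministic 32-bit stream seed derived from the master seed and a salt
# string, so every simulate_* call is a pure function of (config, seed) while
# distinct assays/conditions draw from distinct streams.  Stays below 2^31.
seed_salt <- function(seed, salt) {
  h <- 0
  for (ch in utf8ToInt(salt)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# stopifnot-style check that reports the offending field by name
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid configuration: field `%s` %s", field, msg),
          class = "otognet_config_error")
  }
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# strict BH over a vector that may contain NAs (untested genes)
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  if (length(idx)) out[idx] <- p.adjust(p[idx], method = "BH")
  out
}
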