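#' @keywords internal
"_PACKAGE"

# log(sum(exp(x))) without overflow; used by the CRF forward recursion
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# round-half-up to `digits`, matching how clinical tables are typeset
# (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hichds <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "hichds_error")))
}

# deterministic per-purpose sub-seed derived from a master seed; kept < 2^31
# and collision-free for salts below 65536
derive_seed <- function(seed, salt) {
  (as.integer(seed) %% 32749L) * 65536L + (as.integer(salt) %% 65536L)
}
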