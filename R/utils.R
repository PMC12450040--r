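# internal helpers shared across modules

# round half away from zero (base round() is banker's; reference tables use
# conventional half-up rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_deswax <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "deswax_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE,
                                 non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_deswax("`%s` must be a single finite number", name,
                class = "deswax_domain_error")
  if (positive && x <= 0)
    stop_deswax("`%s` must be > 0 (got %g)", name, x,
                class = "deswax_domain_error")
  if (non_negative && x < 0)
    stop_deswax("`%s` must be >= 0 (got %g)", name, x,
                class = "deswax_domain_error")
  invisible(x)
}

# Halton low-discrepancy sequence (radical-inverse van der Corput per base).
# Deterministic multistart coverage without touching the RNG stream.
halton_sequence <- function(n, dim, bases = c(2L, 3L, 5L, 7L, 11L, 13L)) {
  stopifnot(dim <= length(bases))
  radical_inverse <- function(i, base) {
    f <- 1
    r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  out <- matrix(0, n, dim)
  for (d in seq_len(dim))
    out[, d] <- vapply(seq_len(n), radical_inverse, numeric(1),
                       base = bases[d])
  out
}
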