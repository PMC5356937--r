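# Internal helpers shared across modules.

# Round half away from zero (2.5 -> 3), matching the integer-percent
# grouping convention of germination records; base round() half-to-even
# would merge 86.5 into 86.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

check_counts <- function(n_sown, n_germinated, call = rlang::caller_env()) {
  if (any(n_sown < 1 | n_sown != floor(n_sown))) {
    abort("`n_sown` must be a positive integer.", call = call)
  }
  if (any(n_germinated < 0 | n_germinated != floor(n_germinated))) {
    abort("`n_germinated` must be a non-negative integer.", call = call)
  }
  if (any(n_germinated > n_sown)) {
    abort("`n_germinated` cannot exceed `n_sown`.", call = call)
  }
  invisible(TRUE)
}

check_prob <- function(x, name, open = TRUE, call = rlang::caller_env()) {
  ok <- if (open) x > 0 & x < 1 else x >= 0 & x <= 1
  if (length(x) != 1 || is.na(x) || !ok) {
    abort(sprintf("`%s` must be a probability in %s.", name,
                  if (open) "(0, 1)" else "[0, 1]"), call = call)
  }
  invisible(TRUE)
}
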