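# internal numerical and validation helpers

# log(sum(exp(x))) that is exact for all--Inf input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

assert_count <- function(x, name, min = 0L) {
  if (!is_count(x, min)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s.",
                  name, min, deparse(substitute(x))),
          class = "altrsa_validation_error")
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name),
          class = "altrsa_validation_error")
  }
  as.numeric(x)
}

# Deterministic per-participant RNG streams derived from one master seed, so a
# dataset is reproducible participant-by-participant under partial regeneration.
# Stream layout: design seeds (n), rating seeds (n), then item and group seeds.
derive_streams <- function(seed, n) {
  seeds <- withr::with_seed(seed, sample.int(2147483646L, 2L * n + 2L, replace = FALSE))
  list(
    design = seeds[seq_len(n)],
    rating = seeds[n + seq_len(n)],
    items  = seeds[2L * n + 1L],
    groups = seeds[2L * n + 2L]
  )
}
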