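# Internal numerical helpers.

# log(sum(exp(x))) without overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
}

stop_if_not_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  if (!is.numeric(x) || length(x) == 0L || bad) {
    stop(sprintf("`%s` must be %s", name,
                 if (strict) "positive and finite" else "non-negative and finite"),
         call. = FALSE)
  }
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's
# RNG stream. All generators take explicit seeds; none touch global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) ||
      any(abs(x - round(x)) > 1e-8)) {
    stop(sprintf("`%s` must contain non-negative integer counts", name),
         call. = FALSE)
  }
}
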