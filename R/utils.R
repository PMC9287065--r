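# internal helpers

stopf <- function(fmt, ..., class = NULL) {
  rlang::abort(sprintf(fmt, ...), class = c(class, "swipekin_error"))
}

warnf <- function(fmt, ...) {
  rlang::warn(sprintf(fmt, ...))
}

assert_numeric <- function(x, name) {
  if (!is.numeric(x) || anyNA(x)) {
    stopf("`%s` must be numeric and free of missing values", name)
  }
  invisible(x)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators stay pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}
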