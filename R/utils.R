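# internal helpers

pa_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pamech_error"), call = call))
}

# evaluate `code` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# signed trapezoidal integral of y over x, in sample order
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
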