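## internal helpers shared across modules

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. All stochastic entry points funnel through this
## so that a given seed reproduces results bit-identically regardless of what
## the caller did with the RNG before.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("gentapk_domain_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("gentapk_validation_error", "error")))
}

## canonical number formatting used by all writers (bit-stable round trip)
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    sprintf("%.15g", v)
  }, character(1))
  out
}
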