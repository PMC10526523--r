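# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_config(field, "must be a probability in [0, 1]")
  invisible(x)
}

# Most frequent value; ties broken by the smaller value.
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
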