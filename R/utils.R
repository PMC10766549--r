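# Internal helpers: classed conditions and RNG-state isolation.

fc_stop <- function(message, class) {
  stop(structure(
    class = c(class, "fastcwt_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

fc_domain_error <- function(message) fc_stop(message, "fastcwt_domain_error")
fc_size_error <- function(message) fc_stop(message, "fastcwt_size_error")
fc_format_error <- function(message) fc_stop(message, "fastcwt_format_error")

# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_power_of_two <- function(k) {
  k == round(k) && k >= 1 && bitwAnd(as.integer(k), as.integer(k - 1L)) == 0L
}

next_power_of_two <- function(n) {
  k <- 1L
  while (k < n) k <- k * 2L
  as.integer(k)
}
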