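# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# deterministic child seed, kept inside 32-bit integer range
child_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}
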