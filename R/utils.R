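`%||%` <- function(a, b) if (is.null(a)) b else a

# Local trapezoid quadrature weights for an (irregular) grid.
trapezoid_weights <- function(t) {
  n <- length(t)
  if (n == 1L) return(1)
  dt <- diff(t)
  w <- numeric(n)
  w[1L] <- dt[1L] / 2
  w[n] <- dt[n - 1L] / 2
  if (n > 2L) w[2L:(n - 1L)] <- (dt[-(n - 1L)] + dt[-1L]) / 2
  w
}

# Snapshot the global RNG state and return a closure that restores it, so
# seeded generators leave no trace in the caller's random stream.
preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }
  }
}

fmt_num <- function(x) sprintf("%.10g", x)
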