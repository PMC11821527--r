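#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# stopifnot-style check with a formatted message
.check <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

# centred moving average; edges use the available partial window
.movingAverage <- function(x, window = 5L) {
  n <- length(x)
  if (window <= 1L || n < 2L) return(x)
  h <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- mean(x[lo:hi])
  }
  out
}
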