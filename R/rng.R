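# Reproducible per-component random streams. Each stochastic module draws
# from its own stream derived from (session seed, component id), so a module
# simulated in isolation reproduces its in-session behaviour exactly and no
# module perturbs another's draws.

#' Derived random stream
#'
#' Creates an independent random stream keyed by a session seed and a
#' component identifier. The stream owns a private copy of R's RNG state;
#' drawing from one stream never disturbs the global RNG or other streams.
#'
#' @param seed Session seed (integer).
#' @param component Component identifier, a short string such as
#'   `"adc_noise"`, `"gen3"`, `"scenario"`.
#' @return An object of class `"rng_stream"` with draw methods
#'   [stream_runif()], [stream_rexp()], [stream_rnorm()], [stream_rpois()].
#' @export
rng_stream <- function(seed, component) {
  # fold the component name into a 31-bit sub-seed
  h <- 0
  for (ch in utf8ToInt(as.character(component))) h <- (h * 131 + ch) %% 2147483647
  sub <- as.integer((as.double(seed) * 2654435761 + h) %% 2147483647)
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(sub, kind = "Mersenne-Twister")
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  structure(list(env = env, seed = sub), class = "rng_stream")
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$env$state, envir = globalenv())
  on.exit({
    stream$env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Draw from a derived stream
#' @param stream An [rng_stream()].
#' @param n Number of draws.
#' @param ... Passed to the underlying distribution function.
#' @return Numeric vector of draws.
#' @export
stream_runif <- function(stream, n, ...) with_stream(stream, stats::runif(n, ...))

#' @rdname stream_runif
#' @export
stream_rexp <- function(stream, n, ...) with_stream(stream, stats::rexp(n, ...))

#' @rdname stream_runif
#' @export
stream_rnorm <- function(stream, n, ...) with_stream(stream, stats::rnorm(n, ...))

#' @rdname stream_runif
#' @export
stream_rpois <- function(stream, n, ...) with_stream(stream, stats::rpois(n, ...))
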