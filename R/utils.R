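#' @keywords internal
"_PACKAGE"

## Package-level logging: plain-text messages with a level gate so pipeline
## runs can be made quiet or verbose without touching code.

.ddinet_env <- new.env(parent = emptyenv())
.ddinet_env$log_level <- "info"

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#'
#' Messages below the chosen level are suppressed. Levels, from most to
#' least verbose: `"debug"`, `"info"`, `"warn"`, `"error"`.
#'
#' @param level character scalar, one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level) {
  level <- match.arg(level, names(.log_levels))
  old <- .ddinet_env$log_level
  .ddinet_env$log_level <- level
  invisible(old)
}

ddi_log <- function(level, fmt, ...) {
  if (.log_levels[[level]] >= .log_levels[[.ddinet_env$log_level]]) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' Derive a reproducible substream seed
#'
#' One global seed fans out to independent named streams (features, ATC,
#' pairs, noise, model init, ...) so that changing how many draws one stage
#' makes never perturbs another stage. The derivation is a small
#' deterministic integer hash of the stream name folded into the seed,
#' kept below 2^31 so it is always a valid R seed.
#'
#' @param seed integer master seed.
#' @param name character stream name.
#' @return an integer seed for the named stream.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 1000003
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

## Evaluate expr under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Trapezoidal integral of y over x (x need not be sorted but must be
## monotone along the curve as constructed by callers).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

stable_sigmoid <- function(x) stats::plogis(x)
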