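#' @import methods
#' @importFrom stats rnorm runif approx cor sd setNames rbinom
#' @importFrom utils head modifyList write.csv
#' @importClassesFrom ChemmineR SDF SDFset
NULL

#' Evaluate an expression under a private RNG stream
#'
#' Sets the seed, runs the expression, and restores the caller's
#' `.Random.seed`. All stochastic code in the package goes through this,
#' so a user-level `set.seed()` is never silently consumed.
#'
#' @param seed integer seed (NULL evaluates without touching the RNG).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

## Stable 31-bit string hash (polynomial rolling hash). Used to fan a global
## seed out into independent per-stage streams and to hash atom environments.
MOD31 <- 2147483647

hashString <- function(x, init = 17) {
  h <- init %% MOD31
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% MOD31
  h
}

hashInts <- function(ints, init = 17) {
  h <- init %% MOD31
  for (v in as.numeric(ints)) h <- (h * 1000003 + (v %% MOD31)) %% MOD31
  h
}

#' Derive a stage seed from a global seed
#'
#' Stable fan-out of one global seed into independent named streams, so that
#' every stochastic stage of the pipeline consumes an explicit seed and no
#' stage depends on hidden global RNG state.
#'
#' @param seed integer global seed.
#' @param ... character tags naming the stage (and query, repeat index, ...).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
fanSeed <- function(seed, ...) {
  tag <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  as.integer(hashString(tag) %% (MOD31 - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logMsg <- function(...) {
  message(sprintf("[SpectraMol] %s", sprintf(...)))
}

## cosine of two unit (or general) vectors / matrix rows
cosineSim <- function(a, b) {
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}
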