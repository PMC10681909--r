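#' @importFrom stats rnbinom rbinom rnorm runif rgamma sd var cor
#'   wilcox.test ks.test p.adjust pnorm quantile median setNames
#' @importFrom utils read.table write.table packageVersion
#' @importFrom methods is
NULL

# Classed conditions so callers (and tests) can distinguish bad inputs,
# malformed files and bad configuration.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "ifnregnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
abort_input  <- function(msg) abort(msg, "ifnregnet_input_error")
abort_format <- function(msg) abort(msg, "ifnregnet_format_error")
abort_config <- function(msg) abort(msg, "ifnregnet_config_error")

#' Derive a per-stage random seed from a global seed
#'
#' One global integer seed drives a run; each stage draws from its own
#' substream whose seed is derived deterministically from the global seed and
#' the stage name. All generation uses R's default Mersenne-Twister RNG.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label (e.g. `"expression"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
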