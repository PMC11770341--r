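#' @importFrom stats rnorm runif quantile cor sd kmeans wilcox.test prcomp qnorm
#' @importFrom utils head tail
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG to a fixed state, runs `code`, and restores the caller's RNG
#' state afterwards, so seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit hash of a string (polynomial rolling hash).
str_hash31 <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# Derive an independent sub-seed from a master seed and a stream tag, kept
# below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + str_hash31(tag)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
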