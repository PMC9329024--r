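#' @importFrom stats median prcomp predict qnorm rbinom rnorm runif setNames
#' @importFrom utils read.csv write.csv head
NULL

# Deterministic 32-bit-safe polynomial hash of a character string.
# Used to fan a master seed out to named sub-seeds.
string_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 7
  for (code in utf8ToInt(x)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

#' Derive a named sub-seed from a master seed
#'
#' Every source of randomness in the pipeline draws its own seed as a
#' deterministic function of the master seed and a stable name, so that
#' reordering independent stages never changes any stage's stream.
#'
#' @param master integer master seed.
#' @param name character scalar naming the consumer (e.g. a model name).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, name) {
  as.integer((as.numeric(master) + string_hash(name)) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(expr)
}

# MD5 digest of an arbitrary R object via its serialized form.
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version 3 serialization is stable across sessions for identical objects
  saveRDS(x, f, version = 3)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
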