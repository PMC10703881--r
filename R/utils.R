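#' @import methods
#' @importFrom stats rpois rexp runif rbinom rnorm median quantile sd setNames
#' @importFrom utils read.table write.table head tail
#' @importFrom BiocGenerics sort unlist
NULL

#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from one top-level seed through named
#' substreams, one per operation, so that changing one stage's draws never
#' perturbs another's. Returns a 32-bit integer seed derived from `seed` and
#' `name`.
#'
#' @param seed integer master seed.
#' @param name substream name.
#' @return An integer seed below 2^31.
#' @examples
#' substreamSeed(1, "contact_matrix")
#' @export
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(name) == 1L)
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 31 + cp) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 69621 + h) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; global RNG
# state is restored afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# Wilson/Woolf-style log2 odds ratio with 0.5 continuity correction when any
# cell is zero; returns log2 OR and a 95% CI.
log2OddsRatio <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  lor <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(log2_or = lor / log(2),
       ci_lo = (lor - 1.96 * se) / log(2),
       ci_hi = (lor + 1.96 * se) / log(2))
}
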