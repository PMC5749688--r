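#' @useDynLib appraisalDecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbinom qbinom pt rnorm runif sd fft
#' @importFrom utils write.table read.table head
NULL

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derivation; stays well below 2^31.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + as.double(o)) %% 2147483629
  as.integer(s)
}

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
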