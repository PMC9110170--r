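#' @useDynLib mindfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor fft filter mvfft rnorm runif rbinom sd var
#' @importFrom utils read.csv write.csv
NULL

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness flows through this
# so that nothing perturbs (or depends on) global random state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483629 + 1
}

stop_mf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_mf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
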