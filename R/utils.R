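#' @keywords internal
#' @useDynLib megsam, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  All stochastic operations in the package go
# through this so that a run is reproducible from its configuration alone.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single non-missing number")
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

# Deterministic sub-seed derivation: master seed plus a small structured
# offset, kept well below .Machine$integer.max.
derive_seed <- function(master, subject = 0L, run = 0L, stage = 0L) {
  s <- (as.numeric(master) %% 1e6) * 1000 + subject * 37 + run * 11 + stage
  as.integer(s %% .Machine$integer.max)
}

vnorm <- function(v) sqrt(sum(v^2))

# Component of `v` orthogonal to `radial`, normalized; errors if `v` is
# (numerically) radial.
tangentialize <- function(v, radial) {
  r <- radial / vnorm(radial)
  t <- v - sum(v * r) * r
  n <- vnorm(t)
  if (n < 1e-12) stop("direction is radial; no tangential component")
  t / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
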