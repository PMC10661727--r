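`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stopf("`%s` must be numeric and non-missing", name)
  if (finite && any(!is.finite(x))) stopf("`%s` must be finite", name)
  if (positive && any(x <= 0)) stopf("`%s` must be strictly positive", name)
  invisible(x)
}

## Draw from a lognormal given its median and geometric SD, truncated to
## [lower, upper) by inverse-CDF transform (no rejection needed here).
qlnorm_trunc <- function(p, median, gsd, lower, upper) {
  mu <- log(median)
  sdlog <- log(gsd)
  plo <- stats::plnorm(lower, mu, sdlog)
  phi <- stats::plnorm(upper, mu, sdlog)
  stats::qlnorm(plo + p * (phi - plo), mu, sdlog)
}

## Restore the caller's RNG state on exit so seeded generation does not
## perturb the global stream.
with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  force(code)
}

## Deterministic 32-bit sub-seed for subject i under master seed `seed`;
## affine map keeps seeds distinct within a run and below 2^31.
subject_seed <- function(seed, i) {
  as.integer(((seed %% 2147483647) * 48271 + i * 16807) %% 2147483647)
}
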