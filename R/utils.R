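# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded functions do not perturb global
# reproducibility.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible substream seed below 2^31 from a base seed and a
# stream label, so pipeline stages can be rerun independently.
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483563)
}

# Student-t p-value for the deviation of an observed statistic from a
# permutation null sample: t = (obs - mean(null)) / sd(null), two-sided on
# B - 1 degrees of freedom.  The null SD (not the SE of the null mean) is
# the scale: the question is whether the observation is an ordinary draw
# from the permutation distribution, not whether the null mean equals it.
# A constant null sample makes the statistic degenerate; the limiting
# p-value is 0 when the observed value differs from the constant and 1 when
# it equals it.
tTestAgainstNull <- function(null, observed) {
  if (length(null) < 2L) stop("need at least 2 null draws for a t-test")
  s <- sd(null)
  if (s == 0) return(as.numeric(isTRUE(all.equal(mean(null), observed))))
  tstat <- (observed - mean(null)) / s
  2 * stats::pt(-abs(tstat), df = length(null) - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
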