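# Exact rational arithmetic on non-negative integer counts.
#
# Probabilities in the causal search are ratios of record counts and the
# PC2 decision must never hinge on floating-point rounding, so fractions are
# kept as reduced (numerator, denominator) pairs stored in doubles.  Doubles
# represent integers exactly below 2^53; after gcd reduction the denominators
# that arise here are tiny (lcm of per-context counterfactual counts), but an
# overflow guard aborts rather than silently losing exactness.

.FRAC_MAX <- 2^52

.gcd <- function(a, b) {
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

# reduced fraction num/den, den > 0, num >= 0
.frac <- function(num, den) {
  num <- unname(num)
  den <- unname(den)
  stopifnot(den > 0, num >= 0)
  if (num == 0) return(c(0, 1))
  g <- .gcd(num, den)
  c(num / g, den / g)
}

.frac_add <- function(a, b) {
  num <- a[1] * b[2] + b[1] * a[2]
  den <- a[2] * b[2]
  if (num > .FRAC_MAX || den > .FRAC_MAX)
    stop("exact rational overflow: counts too large for exact arithmetic")
  .frac(num, den)
}

# strict a > b by cross-multiplication (exact)
.frac_gt <- function(a, b) a[1] * b[2] > b[1] * a[2]

.frac_num <- function(f) f[1] / f[2]
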