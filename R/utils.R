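# Internal helpers shared across stages.

# Generalized log on base 2: h(y) = log2((y + sqrt(y^2 + c)) / 2).
# Equals log2(y) exactly as c -> 0 for y > 0; defined for all real y.
glog2 <- function(y, c) log2((y + sqrt(y^2 + c)) / 2)

# Derive a subordinate 31-bit seed from a master seed and a stage offset.
derive_seed <- function(master, offset) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + as.numeric(offset)) %% 2147483647)
}

# Stable small hash of a string, for counter-based per-test seeds.
hash_string <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 1000003
  as.integer(h)
}

# Evaluate expr with the RNG seeded (if seed non-NULL), restoring the
# caller's RNG state afterwards so library code has no global side effects.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Newton inversion of the trigamma function: solve trigamma(x) = y, y > 0.
trigamma_inverse <- function(y) {
  if (y <= 0) stop("trigamma_inverse requires y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}
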