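# Internal helpers shared across modules.

# Derive a reproducible per-stage seed from one global seed. Keeps results
# of different stochastic stages independent while everything flows from a
# single integer.
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 10007 + h * 97) %% (.Machine$integer.max - 1L)) + 1L
}

clip01 <- function(x) pmax(pmin(x, 1), 0)  # x first: keeps dim/dimnames

# Flat (or general) Dirichlet draws, one row per sample.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, ncol = k, byrow = TRUE)
  g / rowSums(g)
}

# Population variance per row of a matrix (divides by n, not n - 1).
rowPopVar <- function(m) {
  mu <- rowMeans(m)
  rowMeans((m - mu)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
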