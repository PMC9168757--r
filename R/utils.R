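# Internal helpers shared across stages.

# Derive a reproducible sub-seed from a master seed. Offsets keep every
# stochastic stage on its own stream; result stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 101L + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson correlation p-value with n - 2 df.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tstat), df = n - 2)
}

# Best bijective mapping of clusters onto classes: enumerate permutations of
# the (small) class set and keep the one maximizing total weight.
best_assignment <- function(weights) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  k <- nrow(weights)
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p) sum(weights[cbind(seq_len(k), p)]), numeric(1))
  perms[[which.max(scores)]]
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}
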