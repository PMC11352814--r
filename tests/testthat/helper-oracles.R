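# Independent oracles used across the suite. These are written naively (plain
# loops, textbook formulas) on purpose, so they share no code path with the
# package implementation they check.

# Barnard unconditional exact p-value by direct enumeration: loop over every
# 2x2 table with the given group sizes, order by the pooled Wald z computed
# from first principles, and maximize the two-sided tail probability over a
# dense nuisance grid.
oracle_barnard <- function(x1, n1, x2, n2,
                           grid = seq(0.0005, 0.9995, by = 0.001)) {
  z_of <- function(a, b) {
    p <- (a + b) / (n1 + n2)
    v <- p * (1 - p) * (1 / n1 + 1 / n2)
    if (v == 0) return(0)
    (b / n2 - a / n1) / sqrt(v)
  }
  z0 <- abs(z_of(x1, x2))
  mask <- matrix(FALSE, n1 + 1, n2 + 1)
  for (a in 0:n1)
    for (b in 0:n2)
      mask[a + 1, b + 1] <- abs(z_of(a, b)) >= z0 - 1e-12
  best <- 0
  for (pi in grid) {
    tot <- sum(outer(dbinom(0:n1, n1, pi), dbinom(0:n2, n2, pi))[mask])
    if (tot > best) best <- tot
  }
  min(1, best)
}

# phi coefficient straight from the (ad - bc) / sqrt(row x column products)
# definition on the 2x2 detection table, oriented so that positive means
# more detections among non-survivors
oracle_phi <- function(ps, ns, pd, nd) {
  a <- ps; b <- ns - ps; c <- pd; d <- nd - pd
  den <- sqrt((a + b) * (c + d) * (a + c) * (b + d))
  if (den == 0) return(0)
  (c * b - a * d) / den
}

# small complete-data cohort for model-level tests: two informative features
# plus noise, controllable class overlap
make_toy_classes <- function(n_per_class, n_noise = 8, sep = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- factor(rep(c("survivor", "non-survivor"), each = n_per_class),
              levels = c("survivor", "non-survivor"))
  X <- cbind(
    s1 = rnorm(n) + ifelse(y == "non-survivor", sep, 0),
    s2 = rnorm(n) - ifelse(y == "non-survivor", sep, 0),
    matrix(rnorm(n * n_noise), n,
           dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
  )
  list(X = X, y = y)
}
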