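# Independent oracles used across tests. These deliberately re-derive each
# quantity by the most literal route available (pair enumeration, normal
# equations, closed forms) so they share no code with the implementation.

# AUROC by brute-force enumeration of all positive-negative pairs
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Weighted least squares through the normal equations, X = [1, x]
wls_normal_equations <- function(x, y, w) {
  X <- cbind(1, x)
  solve(t(X) %*% (w * X), t(X) %*% (w * y))
}

# Log-scale t interval for a geometric mean, written out longhand
gm_ci_oracle <- function(values, level = 0.95) {
  lx <- log(values)
  n <- length(lx)
  half <- qt(1 - (1 - level) / 2, n - 1) * sd(lx) / sqrt(n)
  c(gm = exp(mean(lx)),
    lo = exp(mean(lx) - half),
    hi = exp(mean(lx) + half))
}

# A two-phenotype cohort whose group geometric means are exact by symmetry
two_group_cohort <- function(gm_a, gm_b, n_a = 8L, n_b = 8L, spread = 0.4,
                             classes = c("gNM", "gUM")) {
  sym <- function(n) {
    z <- seq(-1, 1, length.out = n)
    z - mean(z)
  }
  data.frame(
    phenotype = rep(classes, c(n_a, n_b)),
    value = c(gm_a * exp(spread * sym(n_a)), gm_b * exp(spread * sym(n_b)))
  )
}
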