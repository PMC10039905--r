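# Independent oracles used across test files.

# beta-law values by numerical quadrature of the kernel (independent of
# pbeta/dbeta): density(u) = u^(a-1)(1-u)^(b-1)/B, cdf(u) by integrate()
betaKernelOracle <- function(u, a, b, what = c("cdf", "density")) {
  what <- match.arg(what)
  kern <- function(t) t^(a - 1) * (1 - t)^(b - 1)
  B <- exp(lgamma(a) + lgamma(b) - lgamma(a + b))
  if (what == "density") kern(u) / B
  else integrate(kern, 0, u, rel.tol = 1e-10)$value / B
}

# exhaustive enumeration of removing one copy from a trisomic pair
lossEnumOracle <- function(pair) {
  out <- c(heterodisomy = 0, UPID = 0)
  copies <- rep(1:2, times = pair)   # one entry per physical copy
  for (i in seq_along(copies)) {
    res <- pair
    res[copies[i]] <- res[copies[i]] - 1L
    lab <- classifyChromosome(res[1], res[2])
    out[lab] <- out[lab] + 1 / length(copies)
  }
  out
}

# two-sided exact binomial p (minlike) by brute-force summation
binomTwoSidedOracle <- function(x, n, p) {
  mass <- dbinom(0:n, n, p)
  sum(mass[mass <= mass[x + 1] * (1 + 1e-7)])
}

# enumerated per-chromosome copy-total distributions of the founders
founderTotalsOracle <- function(model) {
  switch(model,
    diploid_tripolar = c(`2` = 4/9, `3` = 4/9, `4` = 1/9),
    tetraploid_tripolar = {
      ph <- c(`0` = 1/9, `1` = 4/9, `2` = 4/9)   # per homologue
      tot <- rep(0, 5); names(tot) <- 0:4
      for (i in 0:2) for (j in 0:2)
        tot[as.character(i + j)] <- tot[as.character(i + j)] +
          ph[as.character(i)] * ph[as.character(j)]
      tot
    },
    mitotic_catastrophe = dbinom(0:4, 4, 0.5) |> setNames(0:4)
  )
}
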