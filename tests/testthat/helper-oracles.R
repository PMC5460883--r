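# Independent brute-force oracles used to check the implementation.
# Each one deliberately takes the slowest, most literal route.

# marginal posteriors by exhaustive enumeration over all 3^L state paths
fb_enumerate <- function(e, pi0, trans) {
  n <- nrow(e)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  w <- apply(paths, 1L, function(p) {
    v <- pi0[p[1L]] * e[1L, p[1L]]
    if (n > 1L) for (t in 2:n) v <- v * trans[p[t - 1L], p[t]] * e[t, p[t]]
    v
  })
  post <- matrix(0, n, 3)
  for (t in 1:n) for (s in 1:3)
    post[t, s] <- sum(w[paths[, t] == s])
  post / rowSums(post)
}

# two-sided exact binomial p by minimum-likelihood enumeration
binom_minlik_p <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_enum_p <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  x <- max(0L, k - n2):min(k, m)
  p <- dhyper(x, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(p[p <= obs * (1 + 1e-7)])
}

# two-sided rank-sum p by full enumeration of group assignments (no ties)
wilcox_perm_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  w_all <- apply(combos, 2L, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# literal run-length scan for expression blocks
blocks_bruteforce <- function(states, positions, min_len = 50) {
  out <- NULL
  i <- 1L
  n <- length(states)
  while (i <= n) {
    j <- i
    while (j < n && states[j + 1L] == states[i] &&
           positions[j + 1L] == positions[j] + 1L) j <- j + 1L
    len <- positions[j] - positions[i] + 1L
    if (states[i] != 1L && len >= min_len)
      out <- rbind(out, data.frame(start = positions[i], end = positions[j],
                                   state = states[i], length = len))
    i <- j + 1L
  }
  if (is.null(out)) data.frame(start = integer(), end = integer(),
                               state = integer(), length = integer())
  else out
}

# small hand-built gene model set on one chromosome
toy_genes <- function() {
  gene_model_set(list(
    list(id = "gA", chrom = "2L", strand = "+", start = 1000, end = 3000,
         exons = rbind(c(1000, 1800), c(2200, 3000)),
         utr5 = rbind(c(1000, 1199)), utr3 = rbind(c(2801, 3000))),
    list(id = "gB", chrom = "2L", strand = "+", start = 5000, end = 7000,
         exons = rbind(c(5000, 5900), c(6300, 7000)),
         utr5 = rbind(c(5000, 5199)), utr3 = rbind(c(6801, 7000))),
    list(id = "gC", chrom = "2L", strand = "-", start = 9000, end = 11000,
         exons = rbind(c(9000, 9900), c(10300, 11000)),
         utr5 = rbind(c(10801, 11000)), utr3 = rbind(c(9000, 9199)))))
}
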