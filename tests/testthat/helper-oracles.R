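# Independent brute-force oracles, kept deliberately naive and separate
# from the package's implementations.

# Mann-Whitney by full enumeration: all choose(n, n1) assignments of the
# pooled values to group 1, tail probabilities of the rank sum.
mw_brute_force <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  sums <- apply(combs, 2, function(i) sum(r[i]))
  list(p_greater = mean(sums >= obs), p_less = mean(sums <= obs))
}

# Fisher exact by direct enumeration of all tables with the observed
# margins; two-sided sums probabilities <= observed (with fisher's
# customary relative tolerance).
fisher_brute_force <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(xs, function(x) dhyper(x, c1, n - c1, r1), numeric(1))
  p_obs <- dhyper(a, c1, n - c1, r1)
  list(two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
       greater = sum(probs[xs >= a]),
       less = sum(probs[xs <= a]))
}

# Two-group log-rank observed-minus-expected sums by hand.
logrank_brute_force <- function(g, times, events) {
  g <- as.integer(factor(g)) == 1L
  ts <- sort(unique(times[events]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g)
    d <- sum(events & times == t)
    d1 <- sum(events & times == t & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Cox partial log-likelihood for one covariate, no ties (Breslow = Efron
# when there are no tied event times); maximized by grid refinement.
cox_pl_brute_force <- function(x, times, events) {
  pl <- function(beta) {
    s <- 0
    for (i in which(events)) {
      risk <- times >= times[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
  }
  grid <- seq(-5, 5, by = 0.01)
  b <- grid[which.max(vapply(grid, pl, numeric(1)))]
  fine <- seq(b - 0.01, b + 0.01, by = 1e-5)
  fine[which.max(vapply(fine, pl, numeric(1)))]
}

# tiny cohort fixtures used across files
make_expr_tsv <- function(path, mat, mirnas = rownames(mat),
                          samples = colnames(mat)) {
  df <- data.frame(mirna = mirnas, mat, check.names = FALSE)
  colnames(df) <- c("mirna", samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_maf_tsv <- function(path, df) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
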