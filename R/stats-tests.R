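# Shared statistical machinery: exact Mann-Whitney (tie-aware), Fisher,
# chi-squared and hypergeometric enrichment on 2x2 counts.

# Exact permutation distribution of the rank sum of a size-n1 subset of the
# (mid)ranks r, by dynamic programming over doubled ranks (midranks are
# multiples of 1/2). Returns lower/upper tail probabilities at the observed
# rank sum. Exact also under ties: it enumerates all choose(N, n1) group
# assignments of the observed multiset.
.exact_ranksum_tails <- function(r, n1, observed_sum) {
  r2 <- as.integer(round(2 * r))
  N <- length(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # ways[k+1, s+1] = number of k-subsets with doubled rank sum s
  ways <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  ways[1L, 1L] <- 1
  for (x in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      nz <- which(ways[k, ] > 0)
      if (length(nz)) {
        tgt <- nz + x
        keep <- tgt <= smax + 1L
        ways[k + 1L, tgt[keep]] <- ways[k + 1L, tgt[keep]] + ways[k, nz[keep]]
      }
    }
  }
  counts <- ways[n1 + 1L, ]
  total <- sum(counts)
  obs2 <- as.integer(round(2 * observed_sum))
  sums <- seq_len(smax + 1L) - 1L
  list(p_ge = sum(counts[sums >= obs2]) / total,
       p_le = sum(counts[sums <= obs2]) / total)
}

#' Mann-Whitney U test with an exact tie-aware small-sample path
#'
#' Compares two samples by the Mann-Whitney U statistic. When both group
#' sizes are at most `exact_max` the null distribution is enumerated exactly
#' over all group assignments of the observed values (a permutation test on
#' the tied-rank sum, so ties are handled exactly); otherwise a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y numeric vectors (missing values dropped).
#' @param exact_max largest group size for the exact enumeration path.
#' @return list with `U` (wins of `x` over `y`), group sizes, one-sided
#'   p-values `p_greater` / `p_less` (for `x` stochastically greater/less
#'   than `y`), `p_two` (twice the smaller one-sided value, capped at 1),
#'   group medians, and whether the exact path was used.
#' @examples
#' mw_test(c(4, 5, 6), c(1, 2, 3))$p_greater  # 1/20
#' @export
mw_test <- function(x, y, exact_max = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  rs <- sum(r[seq_len(n1)])
  U <- rs - n1 * (n1 + 1) / 2
  exact <- n1 <= exact_max && n2 <= exact_max
  if (exact) {
    tails <- .exact_ranksum_tails(r, n1, rs)
    p_greater <- tails$p_ge
    p_less <- tails$p_le
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    sigma <- sqrt(sigma2)
    p_greater <- stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
    p_less <- stats::pnorm((U - mu + 0.5) / sigma)
  }
  list(U = unname(U), n1 = n1, n2 = n2,
       p_greater = p_greater, p_less = p_less,
       p_two = min(1, 2 * min(p_greater, p_less)),
       median_x = stats::median(x), median_y = stats::median(y),
       exact = exact)
}

.as_2x2 <- function(t) {
  if (is.matrix(t)) t <- c(t(t))
  t <- as.numeric(t)
  if (length(t) != 4L || any(is.na(t)) || any(t < 0) ||
      any(abs(t - round(t)) > 1e-8))
    stop("a 2x2 table needs four non-negative integer cells", call. = FALSE)
  if (sum(t) == 0) stop("2x2 table total must be positive", call. = FALSE)
  round(t)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test with fixed margins. The two-sided p-value sums the
#' probabilities of all tables no more probable than the observed one (with
#' a small relative tolerance on the comparison). The returned odds ratio is
#' the sample odds ratio `ad/bc` (`Inf` when `bc = 0`), not the conditional
#' MLE.
#'
#' @param t 2x2 table as a matrix or as `c(a, b, c, d)` in row-major order
#'   (row 1 = condition present, column 1 = outcome present).
#' @param sidedness `"two_sided"` (default), `"greater"` or `"less"` for the
#'   association direction of cell `a`.
#' @return list with `p_value`, `odds_ratio` and the table.
#' @examples
#' fisher_exact_2x2(c(86, 60, 65, 108))  # HR defects by score group
#' @export
fisher_exact_2x2 <- function(t, sidedness = c("two_sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  v <- .as_2x2(t)
  a <- v[1]; b <- v[2]; c_ <- v[3]; d <- v[4]
  m <- matrix(v, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("a margin of the 2x2 table is zero; p = 1 by convention",
            call. = FALSE)
    p <- 1
  } else {
    alt <- switch(sidedness, two_sided = "two.sided",
                  greater = "greater", less = "less")
    p <- stats::fisher.test(m, alternative = alt)$p.value
  }
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  list(p_value = p, odds_ratio = or, table = m, sidedness = sidedness)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param t 2x2 table (see [fisher_exact_2x2()]).
#' @param correction apply the Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `p_value`, the table and a
#'   `small_expected` flag set when any expected cell is below 1.
#' @export
chi2_2x2 <- function(t, correction = FALSE) {
  v <- .as_2x2(t)
  m <- matrix(v, nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  small <- any(expected < 1)
  if (small)
    warning("expected cell count below 1; chi-squared approximation is poor",
            call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(m, correct = correction))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       table = m, small_expected = small)
}

#' Hypergeometric enrichment of hits in a gene/miRNA set
#'
#' Fold enrichment and upper-tail p-value for observing `hits_in_set`
#' members of a set of size `set_size` among `hits_total` hits drawn from a
#' universe of `universe` items.
#'
#' @param hits_in_set,set_size,hits_total,universe non-negative integers with
#'   `hits_in_set <= min(set_size, hits_total)` and `hits_total <= universe`.
#' @return list with `fold_enrichment` (0 when there are no hits) and
#'   `p_value` = P(X >= hits_in_set).
#' @examples
#' hypergeom_enrichment(10, 75, 17, 723)
#' @export
hypergeom_enrichment <- function(hits_in_set, set_size, hits_total, universe) {
  if (universe <= 0) stop("universe must be positive", call. = FALSE)
  if (hits_in_set > min(set_size, hits_total) || hits_total > universe ||
      set_size > universe || any(c(hits_in_set, set_size, hits_total) < 0))
    stop("inconsistent hypergeometric counts", call. = FALSE)
  fold <- if (hits_in_set == 0 || hits_total == 0 || set_size == 0) 0 else
    (hits_in_set / set_size) / (hits_total / universe)
  p <- stats::phyper(hits_in_set - 1, hits_total, universe - hits_total,
                     set_size, lower.tail = FALSE)
  list(fold_enrichment = fold, p_value = p,
       hits_in_set = hits_in_set, set_size = set_size,
       hits_total = hits_total, universe = universe)
}
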