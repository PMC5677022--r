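test_that("Kaplan-Meier estimator matches hand product-limit computations", {
  # censored-only data: flat curve at 1
  km <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(km$survival == 1))

  km <- km_estimate(c(1, 2), c(TRUE, TRUE))
  expect_equal(survival_rate_at(km, 1), 0.5, ignore_attr = TRUE)
  expect_equal(survival_rate_at(km, 2), 0, ignore_attr = TRUE)

  # 5 subjects, events at 1 and 3, censored at 2, 4, 5
  km <- km_estimate(c(1, 2, 3, 4, 5), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(survival_rate_at(km, 3), (4 / 5) * (2 / 3),
               ignore_attr = TRUE)

  expect_error(km_estimate(numeric(0), logical(0)), "empty")
})

test_that("survival curves obey the product-limit recursion", {
  set.seed(12)
  km <- km_estimate(rexp(40, 0.3), runif(40) < 0.7)
  recon <- cumprod(1 - km$events / km$at_risk)
  expect_equal(km$survival, recon, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(diff(km$at_risk) <= 0))
})

test_that("step-function evaluation is right-continuous and flags extrapolation", {
  km <- km_estimate(c(1, 2), c(TRUE, TRUE))
  expect_equal(as.numeric(survival_rate_at(km, 1.5)), 0.5)
  expect_equal(as.numeric(survival_rate_at(km, 0)), 1)
  z <- survival_rate_at(km, 10)
  expect_true(attr(z, "extrapolated"))
  expect_false(attr(survival_rate_at(km, 1.5), "extrapolated"))
  expect_error(survival_rate_at(km, -1), ">= 0")
})

test_that("log-rank test matches the hand O-E computation and is time-scale invariant", {
  expect_equal(logrank_test(rep(c("a", "b"), each = 4),
                            rep(c(1, 2, 3, 4), 2),
                            rep(TRUE, 8))$statistic, 0, tolerance = 1e-12)

  g <- rep(c("A", "B"), each = 3)
  t <- c(1, 2, 3, 4, 5, 6); e <- rep(TRUE, 6)
  got <- logrank_test(g, t, e)
  want <- logrank_brute_force(g, t, e)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-9)

  resc <- logrank_test(g, 3.7 * t + 0, e)
  expect_equal(resc$statistic, got$statistic, tolerance = 1e-12)

  expect_error(logrank_test(rep("A", 5), 1:5, rep(TRUE, 5)), "2 groups")
})

test_that("log-rank detects a protective hazard ratio of 0.5 at n = 300", {
  hits <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    g <- rep(0:1, each = 150)
    t <- rexp(300, 0.2 * ifelse(g == 1, 0.5, 1))
    cens <- rexp(300, 0.08)
    hits <- hits + (logrank_test(g, pmin(t, cens), t <= cens)$p_value < 0.05)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("Cox fit matches the brute-force partial-likelihood maximum", {
  # 6 subjects, no ties
  x <- c(0, 1, 0, 1, 1, 0)
  t <- c(5.1, 1.2, 3.4, 2.3, 6.7, 4.5)
  e <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  fit <- cox_fit(data.frame(x = x), t, e)
  oracle <- cox_pl_brute_force(x, t, e)
  expect_equal(unname(fit$coefficients[1]), oracle, tolerance = 1e-4)
  expect_equal(unname(fit$hazard_ratios[1]),
               exp(unname(fit$coefficients[1])))
  expect_true(fit$ci_low[1] <= fit$hazard_ratios[1] &&
                fit$hazard_ratios[1] <= fit$ci_high[1])
})

test_that("Cox fit handles degenerate and pathological inputs explicitly", {
  # identical event patterns in both groups -> coefficient 0
  t <- rep(c(1, 2, 3), 2); e <- rep(TRUE, 6)
  fit <- cox_fit(data.frame(g = rep(0:1, each = 3)), t, e)
  expect_equal(unname(fit$coefficients[1]), 0, tolerance = 1e-8)

  expect_error(cox_fit(data.frame(g = rep(1, 6)), t, e), "constant")

  # perfect separation: all early deaths in one group
  g <- rep(0:1, each = 10)
  tt <- c(1:10, 101:110)
  expect_warning(sep <- cox_fit(data.frame(g = g), tt, rep(TRUE, 20)),
                 "separation")
  expect_true(sep$separation)
})

test_that("Cox recovers the true log-HR on a 50/50 exponential design", {
  set.seed(77)
  n <- 2000
  g <- rep(0:1, each = n / 2)
  beta <- log(0.55)
  t <- rexp(n, 0.2 * exp(beta * g))
  cens <- rexp(n, 0.08)
  fit <- cox_fit(data.frame(g = g), pmin(t, cens), t <= cens)
  se <- sqrt(diag(fit$fit$var))[1]
  expect_lt(abs(unname(fit$coefficients[1]) - beta), 3 * se)
})

test_that("matching scan reproduces the worked traces", {
  # interleaved labels: everything kept
  m <- matched_group_selection(c("A", "B", "A", "B"), 1:4,
                               sample_ids = paste0("S", 1:4))
  expect_equal(sort(c(m$kept_group_a, m$kept_group_b)), paste0("S", 1:4))
  expect_equal(length(m$discarded), 0L)

  # blocked labels: only the middle pair survives
  m <- matched_group_selection(c("A", "A", "B", "B"), 1:4,
                               sample_ids = paste0("S", 1:4))
  expect_equal(m$kept_group_a, "S2")
  expect_equal(m$kept_group_b, "S3")
  expect_setequal(m$discarded, c("S1", "S4"))

  # single label: empty output with warning
  expect_warning(
    m0 <- matched_group_selection(factor(c("A", "A", "A"),
                                         levels = c("A", "B")), 1:3),
    "adjacency")
  expect_equal(length(m0$kept_group_a), 0L)
})

test_that("matched groups are equal-sized and matching is idempotent", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    lab <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("A", "B")
    cv <- rnorm(n)
    ids <- paste0("S", seq_len(n))
    m <- suppressWarnings(matched_group_selection(lab, cv, ids))
    expect_equal(length(m$kept_group_a), length(m$kept_group_b))
    expect_setequal(c(m$kept_group_a, m$kept_group_b, m$discarded), ids)
    kept <- c(m$kept_group_a, m$kept_group_b)
    if (length(kept) >= 2) {
      m2 <- matched_group_selection(m$labels[kept], m$covariate[kept],
                                    kept)
      expect_equal(length(m2$discarded), 0L)
    }
  }
})

test_that("balance test is exact on tiny kept groups", {
  # badly unbalanced kept groups: extreme split of 4 ranks, p = 2/6
  m_bad <- list(kept_group_a = c("S1", "S2"), kept_group_b = c("S3", "S4"),
                covariate = setNames(c(1, 2, 100, 200), paste0("S", 1:4)))
  expect_equal(balance_test(m_bad), 1 / 3)
  m_eq <- matched_group_selection(c("A", "B", "B", "A"), c(1, 1, 2, 2),
                                  sample_ids = paste0("S", 1:4))
  expect_equal(balance_test(m_eq), 1)
})

test_that("score groups matched on mutations stay prognostic; mutation groups matched on score do not", {
  # heavy over-dispersion makes raw burden a noisy proxy of the latent
  # deficiency, the regime the comparison is about
  p_score <- numeric(0); p_mut <- numeric(0)
  for (s in 1:5) {
    co <- simulate_cohort(simulation_config(seed = 900 + s,
                                            mutation_dispersion = 0.5))
    rep_ <- run_pipeline(co$bundle, signature = co$signature)
    p_score <- c(p_score, rep_$matching$score_matched_logrank$p_value)
    p_mut <- c(p_mut, rep_$matching$mutations_matched_logrank$p_value)
  }
  # survival is driven only by the latent deficiency, which the score
  # tracks; raw mutation burden carries no independent signal
  expect_gte(sum(p_score < 0.05), 4)
  expect_gte(sum(p_mut > 0.05), 4)
})
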