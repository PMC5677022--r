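toy_expr <- function(mat) {
  class(mat) <- c("expression_matrix", class(mat))
  mat
}

test_that("score definition: strict median crossings in the signed direction", {
  sig <- signature_spec(paste0("p", 1:6), paste0("n", 1:4))
  n <- 8
  m <- matrix(0, nrow = 10, ncol = n,
              dimnames = list(c(paste0("p", 1:6), paste0("n", 1:4)),
                              paste0("S", 1:n)))
  m[paste0("p", 1:6), ] <- rep(seq_len(n), each = 6)   # medians 4.5
  m[paste0("n", 1:4), ] <- rep(rev(seq_len(n)), each = 4)
  sc <- compute_scores(toy_expr(m), sig)
  # S8 is above all positive medians and below all negative medians
  expect_equal(sc$score[sc$sample_id == "S8"], 10L)
  expect_equal(sc$score[sc$sample_id == "S1"], 0L)

  # a sample exactly at the median everywhere scores 0
  m2 <- matrix(rep(c(1, 2, 3), each = 10), nrow = 10,
               dimnames = list(rownames(m), c("A", "B", "C")))
  m2 <- cbind(m2, D = 2)  # median of {1,2,3,2} is 2 -> all at median
  sc2 <- compute_scores(toy_expr(m2), sig)
  expect_equal(sc2$score[sc2$sample_id == "D"], 0L)
})

test_that("4-sample toy cohort reproduces the hand-evaluated scores", {
  sig <- signature_spec("pos1", "neg1")
  m <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("pos1", "neg1"), paste0("S", 1:4)))
  sc <- compute_scores(toy_expr(m), sig)
  expect_equal(sc$score, c(0L, 0L, 2L, 2L))
})

test_that("missing signature miRNAs error; missing values contribute zero", {
  sig <- signature_spec("present", "absent")
  m <- matrix(1:4, nrow = 1, dimnames = list("present", paste0("S", 1:4)))
  expect_error(compute_scores(toy_expr(m), sig), "absent")

  sig2 <- signature_spec("a", "b")
  m2 <- matrix(c(1, 2, 3, 4, 4, NA, 2, 1), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), paste0("S", 1:4)))
  sc <- compute_scores(toy_expr(m2), sig2)
  expect_equal(sc$score[2], 0L)  # S2's missing b contributes nothing
  expect_true(attr(sc, "missing_flags")["b", "S2"])
})

test_that("scores are rank-based: monotone transforms change nothing; reversal maps s to k - s", {
  set.seed(9)
  sig <- signature_spec(paste0("p", 1:3), paste0("n", 1:2))
  m <- matrix(rnorm(5 * 12), nrow = 5,
              dimnames = list(c(paste0("p", 1:3), paste0("n", 1:2)),
                              paste0("S", 1:12)))
  sc <- compute_scores(toy_expr(m), sig)
  m2 <- m; m2["p2", ] <- 10 * atan(m2["p2", ]) + 3
  expect_equal(compute_scores(toy_expr(m2), sig)$score, sc$score)
  # reversed signature: with continuous values (no ties) s -> k - s
  rev_sig <- signature_spec(paste0("n", 1:2), paste0("p", 1:3))
  sc_rev <- compute_scores(toy_expr(m), rev_sig)
  expect_equal(sc_rev$score, 5L - sc$score)
})

test_that("group assignment uses the declared cutoff and partitions samples", {
  sc <- structure(data.frame(sample_id = paste0("S", 1:11), score = 0:10),
                  k = 10L, class = c("score_result", "data.frame"))
  g <- assign_groups(sc, cutoff = 6)
  expect_equal(g$group[g$score == 5], "low")
  expect_equal(g$group[g$score == 6], "high")
  expect_true(all(g$group %in% c("high", "low")))
  expect_error(assign_groups(sc, cutoff = 11), "cutoff")
})

test_that("an alternate 7-miRNA signature runs through the identical code path", {
  set.seed(2)
  sig7 <- signature_spec(paste0("p", 1:4), paste0("n", 1:3), name = "alt-7")
  m <- matrix(rnorm(7 * 20), nrow = 7,
              dimnames = list(c(paste0("p", 1:4), paste0("n", 1:3)),
                              paste0("S", 1:20)))
  sc <- assign_groups(compute_scores(toy_expr(m), sig7), cutoff = 4)
  expect_equal(attr(sc, "k"), 7L)
  expect_true(all(sc$score >= 0 & sc$score <= 7))
})

test_that("score-level association computes Spearman over level medians", {
  sc <- structure(data.frame(sample_id = paste0("S", 1:9),
                             score = rep(0:2, each = 3)),
                  k = 10L, class = c("score_result", "data.frame"))
  idx <- data.frame(sample_id = paste0("S", 1:9),
                    mutation_count = c(1, 2, 3, 11, 12, 13, 21, 22, 23))
  a <- score_instability_association(sc, idx)
  expect_equal(a$rho, 1)
  expect_equal(a$level_medians, c(2, 12, 22))

  idx$mutation_count <- rep(5, 9)
  a0 <- score_instability_association(sc, idx)
  expect_true(a0$degenerate)
  expect_equal(a0$rho, 0)
  expect_equal(a0$p_value, 1)

  sc2 <- sc; sc2$score <- rep(0:1, length.out = 9)
  expect_error(score_instability_association(sc2, idx), "3 distinct")
})

test_that("response-rate trend is linear-perfect, degenerate-safe and errors below 3 levels", {
  sc <- structure(data.frame(sample_id = paste0("S", 1:12),
                             score = rep(0:3, each = 3)),
                  k = 10L, class = c("score_result", "data.frame"))
  out <- setNames(c(F, F, F, T, F, F, T, T, F, T, T, T), sc$sample_id)
  tr <- response_rate_trend(sc, out)
  expect_equal(tr$r, 1)
  expect_equal(tr$rates, c(0, 1, 2, 3) / 3)

  tr0 <- response_rate_trend(sc, setNames(rep(c(TRUE, FALSE, TRUE), 4),
                                          sc$sample_id))
  expect_true(tr0$degenerate)

  sc$score <- rep(0:1, each = 6)
  expect_error(response_rate_trend(sc, out), "3 score levels")
})

test_that("tumour-normal score comparison gives the enumerated extreme p", {
  r <- compare_tumour_normal_scores(rep(10L, 5), rep(0L, 5))
  expect_equal(r$p_greater, 1 / choose(10, 5))
  expect_equal(compare_tumour_normal_scores(c(1, 2, 3), c(1, 2, 3))$p_two, 1)
})

test_that("normals simulated at zero deficiency score below tumours", {
  co <- simulate_cohort(simulation_config(seed = 31))
  sc <- compute_scores(co$expression_full, co$signature)
  tum <- sc$score[!sc$sample_id %in% co$normal_ids]
  nrm <- sc$score[sc$sample_id %in% co$normal_ids]
  expect_lt(compare_tumour_normal_scores(tum, nrm)$p_greater, 0.05)
})
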