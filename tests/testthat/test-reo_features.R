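# REO values, pair counting, feature matrices and the reversed-stable
# pair screen.

test_that("reo_value implements the sign rule with exact ties", {
  expect_equal(reo_value(5.0, 3.0), 1L)
  expect_equal(reo_value(2.0, 2.0), 0L)
  expect_equal(reo_value(1.0, 4.0), -1L)
  expect_equal(reo_value(c(1, 2, 3), c(2, 2, 2)), c(-1L, 0L, 1L))
  expect_error(reo_value(Inf, 1), "finite")
  expect_error(reo_value(1, NA_real_), "finite")
  # widened tie band
  expect_equal(reo_value(1.0, 1.05, epsilon = 0.1), 0L)
})

test_that("count_pairs is the closed form m(m-1)/2", {
  expect_equal(count_pairs(2), 1)
  expect_equal(count_pairs(10), 45)
  expect_error(count_pairs(1), "integer")
  expect_error(count_pairs(2.5), "integer")
})

test_that("reo_feature_matrix matches the sign rule cell by cell", {
  em <- matrix(c(5, 1, 3,
                 2, 2, 7), nrow = 3,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  pairs <- canonical_pairs(rownames(em))
  f <- reo_feature_matrix(em, pairs)
  expect_equal(dim(f), c(3, 2))
  for (p in seq_len(nrow(pairs))) {
    for (s in colnames(em)) {
      expect_equal(f[p, s],
                   reo_value(em[pairs$id_i[p], s], em[pairs$id_j[p], s]))
    }
  }
  # antisymmetry: a pair given in both directions yields exact negations
  fwd <- reo_feature_matrix(em, data.frame(mirna_i = "a", mirna_j = "b"))
  rev <- reo_feature_matrix(em, data.frame(mirna_i = "b", mirna_j = "a"))
  expect_equal(unname(rev), -unname(fwd))
  expect_error(reo_feature_matrix(em, data.frame(mirna_i = "a",
                                                 mirna_j = "zz")), "zz")
})

test_that("reversal_stability counts majority directions and ties", {
  # perfect reversal
  rs <- reversal_stability(rep(c(1L, -1L), each = 10),
                           rep(c("control", "case"), each = 10))
  expect_equal(rs, list(control_direction = 1L, f_control = 1.0,
                        f_case = 1.0))
  # mixed counts with ties in the denominators only
  row <- c(rep(1L, 7), rep(-1L, 2), 0L,    # controls
           rep(-1L, 6), rep(1L, 3), 0L)    # cases
  labs <- rep(c("control", "case"), each = 10)
  rs <- reversal_stability(row, labs)
  expect_equal(rs$control_direction, 1L)
  expect_equal(rs$f_control, 0.7)
  expect_equal(rs$f_case, 0.6)
  # exact control tie breaks toward +1
  tied <- reversal_stability(c(rep(c(1L, -1L), 5), rep(-1L, 10)), labs)
  expect_equal(tied$control_direction, 1L)
  expect_error(reversal_stability(rep(1L, 5), rep("case", 5)), "class")
  # direction antisymmetry: negating the row flips the direction only
  neg <- reversal_stability(-row, labs)
  expect_equal(neg$control_direction, -1L)
  expect_equal(neg$f_control, rs$f_control)
  expect_equal(neg$f_case, rs$f_case)
})

test_that("screen output is control-majority directed and sorted", {
  coh <- small_cohort(seed = 4)
  scr <- screen_reversed_stable(coh$expression, coh$meta, 0.60)
  expect_true(nrow(scr) >= 1)
  mins <- pmin(scr$f_control, scr$f_case)
  expect_true(all(diff(mins) <= 0))
  expect_true(all(scr$f_control >= 0.6 & scr$f_case >= 0.6))
  # every reported pair really has control majority in the stated direction
  f <- reo_feature_matrix(coh$expression, scr)
  is_ctrl <- coh$meta$label == "control"
  expect_true(all(rowMeans(f[, is_ctrl, drop = FALSE] == 1) ==
                    scr$f_control))
  expect_error(screen_reversed_stable(coh$expression, coh$meta, 0.5),
               "threshold")
  expect_error(screen_reversed_stable(coh$expression, coh$meta, 1.01),
               "threshold")
})

test_that("screen equals the naive triple-loop oracle on small instances", {
  for (seed in 1:5) {
    coh <- simulate_cohort(synthetic_spec(n_case = 15, n_control = 15,
                                          m_mirnas = 12, planted_pairs = 3,
                                          fidelity = 0.8, seed = seed))
    got <- screen_reversed_stable(coh$expression, coh$meta, 0.60)
    ref <- naive_screen(coh$expression, coh$meta$label, 0.60)
    key <- function(d) d[order(d$mirna_i, d$mirna_j), , drop = FALSE]
    expect_equal(key(got)[c("mirna_i", "mirna_j")],
                 key(ref)[c("mirna_i", "mirna_j")],
                 ignore_attr = TRUE)
    expect_equal(key(got)$f_control, key(ref)$f_control)
    expect_equal(key(got)$f_case, key(ref)$f_case)
  }
})

test_that("screen block size does not change the result", {
  coh <- small_cohort(seed = 6, m = 20, planted = 3, n = 25)
  full <- screen_reversed_stable(coh$expression, coh$meta)
  blocked <- screen_reversed_stable(coh$expression, coh$meta,
                                    block_size = 7L)
  expect_identical(full, blocked)
})

test_that("a single tie excludes a pair at threshold 1.0", {
  em <- matrix(c(2, 1,  2, 1,  2, 2,   # controls: two +1, one tie
                 1, 2,  1, 2,  1, 2),  # cases: all -1
               nrow = 2,
               dimnames = list(c("a", "b"), paste0("s", 1:6)))
  meta <- cohort_metadata(paste0("s", 1:6),
                          rep(c("control", "case"), each = 3),
                          rep(70, 6), rep(0, 6))
  expect_equal(nrow(screen_reversed_stable(em, meta, threshold = 1.0)), 0)
  scr <- screen_reversed_stable(em, meta, threshold = 0.6)
  expect_equal(scr$f_control, 2 / 3)
  expect_equal(scr$f_case, 1.0)
})

test_that("label permutation on a null cohort matches the binomial tail", {
  # equal baselines: every pair's REO is a fair coin per sample
  set.seed(31)
  n <- 15
  em <- matrix(rnorm(10 * 2 * n), nrow = 10,
               dimnames = list(sprintf("m%02d", 1:10),
                               sprintf("s%02d", seq_len(2 * n))))
  labs <- rep(c("control", "case"), each = n)
  counts <- integer(50)
  for (r in seq_len(50)) {
    meta <- cohort_metadata(colnames(em), sample(labs), rep(70, 2 * n),
                            rep(0, 2 * n))
    counts[r] <- nrow(screen_reversed_stable(em, meta, 0.60))
  }
  # P(pass) = 2 P(Bin(n, 1/2) >= ceil(0.6 n))^2 per pair under the null
  tail_p <- pbinom(ceiling(0.6 * n) - 1, n, 0.5, lower.tail = FALSE)
  expected <- count_pairs(10) * 2 * tail_p^2
  expect_lt(abs(mean(counts) - expected), 4)
})
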