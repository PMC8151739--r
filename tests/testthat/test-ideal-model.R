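test_that("trials rank by comfort total with deterministic tie-breaks", {
  ts <- list(quick_trial(16, "b"), quick_trial(17, "a"),
             quick_trial(16, "c"), quick_trial(16, "d"))
  ranked <- rank_trials(ts, "supine")
  expect_equal(vapply(ranked, function(t) t$comfort$total, numeric(1)),
               c(17, 16, 16, 16))
  expect_equal(ranked[[1]]$pillow_id, "a")
  # equal totals and sub-scores: ordered by trial id
  same <- list(quick_trial(12, "z"), quick_trial(12, "y"), quick_trial(12, "x"))
  expect_equal(vapply(rank_trials(same, "supine"), function(t) t$pillow_id,
                      character(1)), c("x", "y", "z"))
  expect_equal(rank_trials(list(quick_trial(8, "only")), "supine")[[1]]$pillow_id,
               "only")
  expect_error(rank_trials(list(), "supine"), "no valid trials")
})

test_that("top-fraction count follows the configured rounding", {
  mk <- function(n) lapply(seq_len(n), function(i)
    quick_trial(4 + (i %% 16), sprintf("t%02d", i)))
  i42 <- build_ideal_matrix(mk(42), "supine", fraction = 0.10)
  expect_length(i42$source_trial_ids, 4)   # floor(4.2), the study's count
  i42c <- build_ideal_matrix(mk(42), "supine", fraction = 0.10,
                             round_mode = "ceil")
  expect_length(i42c$source_trial_ids, 5)
  i40 <- build_ideal_matrix(mk(40), "supine", fraction = 0.10,
                            round_mode = "ceil")
  expect_length(i40$source_trial_ids, 4)
  # min_keep floor
  i3 <- build_ideal_matrix(mk(3), "supine", fraction = 0.10)
  expect_length(i3$source_trial_ids, 1)
})

test_that("ideal matrix averages aligned sources", {
  v <- matrix(0, 6, 6); v[3:4, 3:4] <- c(2, 3, 4, 5)
  m <- pmx(v)
  # identical matrices, fraction 1: the ideal is that matrix (centered)
  ts <- list(quick_trial(18, "a", matrix = m), quick_trial(17, "b", matrix = m))
  ideal <- build_ideal_matrix(ts, "supine", fraction = 1)
  expect_equal(ideal$matrix$values, align_to_center(m)$matrix$values)
  # a 1-cell translated copy aligns back onto the original
  v2 <- matrix(0, 6, 6); v2[4:5, 4:5] <- c(2, 3, 4, 5)
  ts2 <- list(quick_trial(18, "a", matrix = m),
              quick_trial(17, "b", matrix = pmx(v2)))
  ideal2 <- build_ideal_matrix(ts2, "supine", fraction = 1)
  expect_equal(ideal2$matrix$values, align_to_center(m)$matrix$values)
  # mismatched grids are reported with the offending trial id
  bad <- list(quick_trial(18, "a", matrix = m),
              quick_trial(17, "b", matrix = const_matrix(2, 3, 3)))
  expect_error(build_ideal_matrix(bad, "supine"), "b/S")
})

test_that("cosine similarity matches hand values and its invariants", {
  A <- pmx(matrix(c(1, 0, 0, 1), 2, 2))
  B <- const_matrix(1, 2, 2)
  expect_equal(cosine_similarity(A, B), 2 / (sqrt(2) * 2), tolerance = 1e-12)
  expect_equal(cosine_similarity(A, A), 1.0)
  # disjoint supports
  C <- pmx(matrix(c(1, 0, 0, 0), 2, 2), threshold = 0)
  D <- pmx(matrix(c(0, 0, 0, 1), 2, 2), threshold = 0)
  expect_equal(cosine_similarity(C, D), 0.0)
  # scale invariance and symmetry
  set.seed(3)
  X <- pmx(matrix(runif(16), 4, 4)); Y <- pmx(matrix(runif(16), 4, 4))
  Xs <- pmx(3.7 * X$values)
  expect_equal(cosine_similarity(X, Xs), 1.0, tolerance = 1e-12)
  expect_equal(cosine_similarity(X, Y), cosine_similarity(Y, X),
               tolerance = 1e-12)
  expect_error(cosine_similarity(pmx(matrix(0, 2, 2)), A), "zero-norm")
  expect_error(cosine_similarity(const_matrix(1, 3, 3), X), "shape")
})
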