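test_that("nine-level scores convert to a complementary matrix", {
  a <- matrix(c(5, 3, 3, 5), 2, 2)
  v <- to_complementary(judgment_matrix(a, "nine_level"))
  expect_equal(unname(v$entries), matrix(0.5, 2, 2))
  a2 <- matrix(c(5, 1, 9, 5), 2, 2)  # a_12 = 9, a_21 = 1
  v2 <- to_complementary(judgment_matrix(a2, "nine_level"))
  expect_equal(v2$entries[1, 2], 0.9)
  # V'_ij + V'_ji = 1 for arbitrary score matrices
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:7, 1)
    a <- matrix(runif(n * n, 1, 9), n, n); diag(a) <- 5
    v <- to_complementary(judgment_matrix(a, "nine_level"))$entries
    expect_equal(unname(v + t(v)), matrix(1, n, n), tolerance = 1e-12)
  }
})

test_that("row-sum weights match hand values and always sum to 1", {
  u <- judgment_matrix(matrix(0.5, 3, 3), "complementary")
  expect_equal(unname(fahp_weights(u)$weights), rep(1 / 3, 3))
  m2 <- judgment_matrix(matrix(c(0.5, 0.1, 0.9, 0.5), 2, 2), "complementary")
  expect_equal(unname(fahp_weights(m2)$weights), c(0.7, 0.3))
  set.seed(14)
  for (i in 1:1000) {
    n <- sample(2:9, 1)
    w <- fahp_weights(random_complementary(n))$weights
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
  }
  bad <- matrix(c(0.5, 0.3, 0.9, 0.5), 2, 2)
  expect_error(judgment_matrix(bad, "complementary"), "not complementary")
})

test_that("raising a comparison raises that partition's weight", {
  set.seed(30)
  jm <- random_complementary(5)
  w0 <- fahp_weights(jm)$weights
  v <- jm$entries
  v[2, 4] <- min(1, v[2, 4] + 0.05); v[4, 2] <- 1 - v[2, 4]
  w1 <- fahp_weights(judgment_matrix(v, "complementary"))$weights
  expect_gt(w1[[2]], w0[[2]])
  expect_lt(w1[[4]], w0[[4]])
  expect_equal(w1[[1]], w0[[1]])  # untouched rows keep their weight
})

test_that("compatibility index is zero iff additively consistent", {
  # matrix built from a weight vector via the consistency relation
  w <- c(0.4, 0.35, 0.25)
  n <- 3
  v <- outer(w, w, function(a, b) 0.5 + (n - 1) * (a - b))
  jm <- judgment_matrix(v, "complementary")
  chk <- consistency_check(jm)
  expect_equal(chk$ci, 0, tolerance = 1e-12)
  expect_true(chk$pass)
  expect_equal(unname(fahp_weights(jm)$weights), w, tolerance = 1e-12)
  # uniform indifference is trivially consistent
  expect_equal(consistency_check(judgment_matrix(matrix(0.5, 4, 4),
                                                 "complementary"))$ci, 0)
  # generic matrix: index agrees with an independent double-loop evaluation
  set.seed(77)
  jm2 <- random_complementary(6)
  w2 <- fahp_weights(jm2)
  got <- consistency_check(jm2, w2)$ci
  acc <- 0; v2 <- jm2$entries
  for (i in 1:5) for (j in (i + 1):6)
    acc <- acc + abs(v2[i, j] - 0.5 - 5 * (w2$weights[[i]] - w2$weights[[j]]))
  expect_equal(got, 2 * acc / 30, tolerance = 1e-12)
  expect_gt(got, 0)
})

test_that("hierarchy combination preserves normalization", {
  wc <- weight_vector(c(X = 0.6, Y = 0.4))
  expect_equal(combine_hierarchy(weight_vector(c(g = 1), "B"),
                                 list(g = wc))$weights,
               c(X = 0.6, Y = 0.4))
  wb <- weight_vector(c(g1 = 0.5, g2 = 0.5), "B")
  half <- weight_vector(c(a = 0.5, b = 0.5))
  out <- combine_hierarchy(wb, list(g1 = half,
                                    g2 = weight_vector(c(c = 0.5, d = 0.5))))
  expect_equal(unname(out$weights), rep(0.25, 4))
  expect_error(combine_hierarchy(wb, list(g1 = half)), "one weight vector per")
  # the reference table decomposes into posture blocks 0.320 / 0.680
  ref <- reference_partition_weights()$weights
  sup <- ref[c("A1", "A2", "A3")]; lat <- ref[c("B1", "B2", "B3", "B4")]
  expect_equal(sum(sup), 0.320, tolerance = 1e-9)
  expect_equal(sum(lat), 0.680, tolerance = 1e-9)
  re <- combine_hierarchy(
    weight_vector(c(supine = sum(sup), lateral = sum(lat)), "B"),
    list(supine = weight_vector(sup / sum(sup)),
         lateral = weight_vector(lat / sum(lat))))
  expect_equal(re$weights[names(ref)], ref, tolerance = 1e-12)
})

test_that("expert aggregation averages and renormalizes", {
  w <- weight_vector(c(A = 0.3, B = 0.7))
  expect_equal(aggregate_experts(list(w))$weights, w$weights)
  expect_equal(aggregate_experts(list(w, w))$weights, w$weights)
  w2 <- weight_vector(c(A = 0.5, B = 0.5))
  expect_equal(unname(aggregate_experts(list(w, w2))$weights), c(0.4, 0.6))
  expect_error(aggregate_experts(list(w, weight_vector(c(A = 0.5, C = 0.5)))),
               "different partition sets")
  # the packaged reference: temporal bone maximal, posterior parietal minimal
  ref <- reference_partition_weights()$weights
  expect_equal(names(which.max(ref)), "B3")
  expect_equal(names(which.min(ref)), "A3")
  expect_equal(unname(ref[["B3"]]), 0.213, tolerance = 1e-9)
  expect_equal(unname(ref[["A3"]]), 0.082, tolerance = 1e-9)
})
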