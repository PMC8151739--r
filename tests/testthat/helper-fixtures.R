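# shared fixture builders: tiny matrices, quick trials, random complementary
# judgment matrices

pmx <- function(values, pitch_cm = 1, threshold = 0.1) {
  pressure_matrix(values, pitch_cm = pitch_cm,
                  contact_threshold_kpa = threshold)
}

const_matrix <- function(value, nr = 4, nc = 4, pitch_cm = 1) {
  pmx(matrix(value, nr, nc), pitch_cm)
}

quick_trial <- function(total, id = "T1", posture = "supine",
                        matrix = const_matrix(2), subscores = NULL) {
  if (is.null(subscores)) {
    base <- total %/% 4
    rem <- total - 4 * base
    subscores <- base + c(rep(1, rem), rep(0, 4 - rem))
  }
  trial_record(id, "S", posture, matrix,
               comfort_score(subscores[1], subscores[2], subscores[3],
                             subscores[4]))
}

random_complementary <- function(n) {
  v <- matrix(0.5, n, n)
  up <- upper.tri(v)
  v[up] <- runif(sum(up))
  v[lower.tri(v)] <- (1 - t(v))[lower.tri(v)]
  judgment_matrix(v, "complementary")
}

# dense grid-search oracle for the 1-D fuzzy c-means objective, c = 2, m = 2:
# for fixed centers the optimal memberships give
#   J(v) = sum_i [ sum_k d_ik^-2 ]^-1   (with crisp handling of d = 0)
fcm_grid_oracle <- function(x, grid_n = 200) {
  rng <- range(x)
  centers <- seq(rng[1], rng[2], length.out = grid_n)
  best <- Inf
  for (v1 in centers) {
    d1 <- (x - v1)^2
    for (v2 in centers) {
      d2 <- (x - v2)^2
      zero <- pmin(d1, d2) < .Machine$double.eps
      ji <- ifelse(zero, 0, 1 / (1 / d1 + 1 / d2))
      J <- sum(ji)
      if (J < best) best <- J
    }
  }
  best
}

# rank-correlation oracle: Spearman's rho as Pearson correlation of ranks
spearman_oracle <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
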