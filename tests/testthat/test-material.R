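test_that("stiffness requirement is force over compression", {
  expect_equal(required_stiffness(10, 20), 0.5)
  expect_equal(required_stiffness(20, 20), 2 * required_stiffness(10, 20))
  expect_error(required_stiffness(10, 0), "> 0")
})

test_that("partition forces convert pressure to newtons and conserve", {
  # one labeled cell at 1 kPa on a 1 cm pitch grid: 0.1 N
  v <- matrix(0, 2, 2); v[1, 1] <- 1
  labs <- matrix(0L, 2, 2); labs[1, 1] <- 1L
  f <- partition_force(pmx(v), partition_map(labs, c("1" = "X"), "supine"))
  expect_equal(f[["X"]], 0.1)
  # constant 2 kPa over 50 cells of 1 cm^2: 10 N
  v2 <- matrix(2, 5, 10)
  f2 <- partition_force(pmx(v2), partition_map(matrix(1L, 5, 10),
                                               c("1" = "ALL"), "supine"))
  expect_equal(f2[["ALL"]], 10)
  # forces are additive over partitions, including background
  set.seed(4)
  v3 <- matrix(runif(64, 0, 3), 8, 8)
  labs3 <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  labs3[1, 1] <- 1L
  pm3 <- partition_map(labs3, c("1" = "P1", "2" = "P2", "3" = "P3"), "supine")
  m3 <- pmx(v3, pitch_cm = 0.7)
  f3 <- partition_force(m3, pm3)
  expect_equal(sum(f3), sum(v3) * 0.49 * 0.1, tolerance = 1e-12)
})

test_that("power-law fit recovers the reference coefficients and exact data", {
  cal <- reference_elastic_calibration()
  expect_equal(cal$fitted_a, 3.613, tolerance = 5e-4)
  expect_equal(cal$fitted_b, -0.769, tolerance = 5e-4)
  # independent slope oracle on the log pairs
  ld <- log(cal$pairs$diameter_mm); lk <- log(cal$pairs$k)
  slope <- sum((lk - mean(lk)) * (ld - mean(ld))) / sum((lk - mean(lk))^2)
  expect_equal(cal$fitted_b, slope, tolerance = 1e-12)
  # noiseless power-law data round-trips exactly
  d <- seq(5, 25, by = 2.5)
  k <- (d / 2)^(1 / -0.5)      # d = 2 k^-0.5
  fit <- fit_power_law(d, k)
  expect_equal(unname(fit["a"]), 2, tolerance = 1e-9)
  expect_equal(unname(fit["b"]), -0.5, tolerance = 1e-9)
  expect_error(fit_power_law(c(1, 2), c(3, 4)), "at least 3")
  expect_error(fit_power_law(c(1, 2, -1), c(3, 4, 5)), "positive")
})

test_that("pore diameters follow the fitted curve and clamp to its domain", {
  cal <- reference_elastic_calibration()
  d <- pore_diameter(0.541, cal)
  expect_equal(as.numeric(d), 6.0)             # 5.80 before clamping
  expect_true(attr(d, "clamped"))
  expect_equal(unname(cal$fitted_a * 0.541^cal$fitted_b), 5.80,
               tolerance = 5e-3)
  cal_mid <- generate_calibration(a = 10, b = -0.5)
  expect_equal(as.numeric(pore_diameter(1, cal_mid)), 10,
               tolerance = 1e-9)           # k = 1 -> d = a (unclamped)
  ks <- c(0.12, 0.2, 0.3, 0.45)
  ds <- pore_diameter(ks, cal)
  expect_true(all(diff(ds) < 0))           # larger k -> smaller pore
  expect_error(pore_diameter(-1, cal), "> 0")
})

test_that("compressed geometry reproduces reference stiffness magnitudes", {
  nodes <- contour_nodes("MS", c(Z = 55), foam_height_mm = 110)
  expect_error(contour_nodes("MS", c(Z = -5)), "0, foam height")
  cfg <- generator_config()
  im <- synthetic_ideal_matrix("supine", cfg, seed = 42)
  m <- im$matrix
  f <- fcm(m$values[contact_mask(m)], c = 3, seed = 42)
  pm <- name_partitions(label_map(f, m, posture = "supine"), m)
  good <- generate_contour_nodes("MS", seed = 1)
  geo <- compressed_geometry(good, im, pm)
  expect_equal(geo$compressed_height_mm + geo$height_change_mm,
               rep(110, nrow(geo)))
  ref <- reference_partition_stiffness()
  for (i in seq_len(nrow(geo))) {
    kref <- ref$k_calculated[ref$partition == geo$partition[i]]
    expect_lt(abs(geo$required_k[i] - kref) / kref, 0.15)
  }
  # zero depth is rejected
  zero <- good; zero$depth_mm["A1"] <- 0
  expect_error(compressed_geometry(zero, im, pm), "not compressed")
})

test_that("pore layouts are staggered, in-range, and partition-consistent", {
  labs <- rbind(matrix(1L, 10, 20), matrix(2L, 10, 20))
  pm <- partition_map(labs, c("1" = "SOFT", "2" = "FIRM"), "supine")
  cal <- reference_elastic_calibration()
  geo <- data.frame(partition = c("SOFT", "FIRM"),
                    total_force_N = c(5, 5),
                    height_change_mm = c(50, 16),
                    compressed_height_mm = c(60, 94),
                    required_k = c(0.1, 0.3125))
  class(geo) <- c("partition_geometry", "data.frame")
  layout <- pore_layout(geo, pm, cal, bounds_mm = c(400, 300))
  expect_true(all(layout$diameter_mm >= 6 & layout$diameter_mm <= 21))
  # the softer (lower-k) partition gets the larger pores
  expect_gt(unique(layout$diameter_mm[layout$partition == "SOFT"]),
            unique(layout$diameter_mm[layout$partition == "FIRM"]))
  # hole count equals a brute-force staggered lattice enumeration
  pitch <- cal$pitch_mm
  ys <- seq(pitch / 2, 300 - pitch / 2, by = pitch * sqrt(3) / 2)
  count <- 0
  for (r in seq_along(ys)) {
    off <- if (r %% 2 == 0) pitch / 2 else 0
    xs <- seq(pitch / 2 + off, 400 - pitch / 2, by = pitch)
    count <- count + length(xs)   # every lattice point is over a partition
  }
  expect_equal(nrow(layout), count)
  # no two holes closer than the pitch (within numerical slack)
  dmat <- as.matrix(stats::dist(layout[, c("x_mm", "y_mm")]))
  diag(dmat) <- Inf
  expect_gte(min(dmat), pitch - 1e-9)
})
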