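test_that("spatially separate blobs of one pressure level split into regions", {
  v <- matrix(0, 8, 8)
  v[2:3, 2:3] <- 3; v[6:7, 6:7] <- 3   # two blobs of the high level
  v[5, 2] <- 0.5; v[5, 3] <- 0.5       # one low-level blob
  m <- pmx(v)
  f <- fcm(v[contact_mask(m)], c = 2, seed = 1)
  pm <- label_map(f, m, posture = "supine", min_region_cells = 1)
  # low-level blob + two high-level blobs
  expect_equal(length(partition_labels(pm)), 3)
})

test_that("label_map recovers nested constant zones almost exactly", {
  set.seed(21)
  truth <- matrix(1L, 18, 18)
  truth[7:18, ] <- 2L
  truth[13:18, ] <- 3L
  v <- matrix(c(1, 2.5, 4)[truth], 18, 18) + rnorm(324, 0, 0.02)
  m <- pmx(v, threshold = 0.1)
  f <- fcm(v[contact_mask(m)], c = 3, seed = 2)
  pm <- label_map(f, m, posture = "supine")
  expect_equal(length(partition_labels(pm)), 3)
  agree <- mean(pm$labels == truth)
  expect_gte(agree, 0.99)
})

test_that("partitions are named by position and pressure", {
  # three stacked bands, neck edge at row 1 -> A1, A2, A3 in order
  truth <- matrix(1L, 18, 18); truth[7:18, ] <- 2L; truth[13:18, ] <- 3L
  v <- matrix(c(2, 4, 1)[truth], 18, 18)
  m <- pmx(v, threshold = 0.1)
  f <- fcm(v[contact_mask(m)], c = 3, seed = 2)
  pm <- name_partitions(label_map(f, m, posture = "supine"), m)
  name_at <- function(pm, i, j) unname(pm$names[as.character(pm$labels[i, j])])
  expect_equal(name_at(pm, 2, 9), "A1")
  expect_equal(name_at(pm, 9, 9), "A2")
  expect_equal(name_at(pm, 16, 9), "A3")

  # lateral: the highest-mean-pressure central region is the temporal B3
  v <- matrix(0, 20, 20)
  v[2:5, 8:13] <- 2.5     # cervical strip at the neck edge
  v[9:14, 2:5] <- 2.45    # jaw island, anterior side
  v[8:15, 9:16] <- 5      # temporal zone, carries the peak
  v[17:19, 8:13] <- 1     # parietal zone
  m <- pmx(v, threshold = 0.1)
  f <- fcm(v[contact_mask(m)], c = 3, seed = 3)
  pml <- name_partitions(label_map(f, m, posture = "lateral"), m)
  expect_setequal(unname(pml$names), c("B1", "B2", "B3", "B4"))
  expect_equal(name_at(pml, 3, 10), "B1")
  expect_equal(name_at(pml, 11, 3), "B2")
  expect_equal(name_at(pml, 11, 12), "B3")
  expect_equal(name_at(pml, 18, 10), "B4")
  # strict mode rejects the wrong expected count
  expect_error(name_partitions(pml, m, strict = TRUE), NA)
  pml$posture <- "supine"
  expect_error(name_partitions(pml, m, strict = TRUE), "expected 3")
})

test_that("surplus regions get deterministic suffixed names", {
  v <- matrix(0, 22, 22)
  v[2:4, 9:13] <- 2.5; v[7:10, 9:14] <- 5; v[13:15, 3:6] <- 2.4
  v[13:15, 16:19] <- 1.2; v[19:21, 9:13] <- 1
  m <- pmx(v, threshold = 0.1)
  f <- fcm(v[contact_mask(m)], c = 3, seed = 4)
  pm <- label_map(f, m, posture = "lateral", min_region_cells = 1)
  expect_equal(length(partition_labels(pm)), 5)
  expect_error(name_partitions(pm, m), "expected 4")
  named <- name_partitions(pm, m, strict = FALSE)
  expect_setequal(unname(named$names), c("B1", "B2", "B3", "B4", "B4a"))
})

test_that("small fragments merge into the neighbour with the longest boundary", {
  v <- matrix(2, 10, 10)
  v[5, 5] <- 6  # single high-value speck inside a uniform field
  m <- pmx(v)
  f <- fcm(v[contact_mask(m)], c = 2, seed = 1)
  pm <- label_map(f, m, posture = "supine", min_region_cells = 3)
  expect_equal(length(partition_labels(pm)), 1)
  expect_true(all(pm$labels == 1L))
})

test_that("canonical synthetic ideal matrices partition into 3 + 4 regions", {
  cfg <- generator_config()
  counts <- c(supine = 3L, lateral = 4L)
  for (post in names(counts)) {
    im <- synthetic_ideal_matrix(post, cfg, seed = 42)
    m <- im$matrix
    f <- fcm(m$values[contact_mask(m)], c = 3, seed = 42)
    pm <- name_partitions(label_map(f, m, posture = post), m)
    expect_equal(length(partition_labels(pm)), counts[[post]])
    # relabeling invariance: the map is canonical given sorted centers
    f2 <- fcm(m$values[contact_mask(m)], c = 3, seed = 99)
    pm2 <- label_map(f2, m, posture = post)
    expect_equal(pm2$labels, pm$labels)
  }
})
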