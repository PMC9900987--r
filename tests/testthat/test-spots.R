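# render n Gaussian spots into a blank volume via the simulator's kernel
blob_volume <- function(d, centers, amp = 1000, sigma = 0.25,
                        voxelSize = c(0.5, 0.21, 0.21)) {
  v <- array(0, d)
  sig <- sigma / voxelSize
  for (i in seq_len(nrow(centers))) {
    # modifies v in place (void C++ routine)
    MuxFISH:::cpp_add_blob(v, d, centers[i, 1] - 1, centers[i, 2] - 1,
                           centers[i, 3] - 1, sig[1], sig[2], sig[3],
                           amp, 4)
  }
  v
}

test_that("a single blob yields one detection at its centre", {
  d <- c(12L, 30L, 30L)
  v <- blob_volume(d, rbind(c(6, 15, 15)))
  st <- detectSpots(v)
  expect_identical(nrow(st), 1L)
  expect_equal(c(st$z, st$y, st$x), c(6, 15, 15), ignore_attr = TRUE)
  expect_gt(st$intensity, 500)
})

test_that("an empty volume yields no detections", {
  st <- detectSpots(array(0, c(8, 16, 16)))
  expect_identical(nrow(st), 0L)
  st2 <- detectSpots(array(100, c(8, 16, 16)))   # flat is featureless too
  expect_identical(nrow(st2), 0L)
})

test_that("all well-separated blobs are found, and none invented", {
  set.seed(31)
  d <- c(14L, 40L, 40L)
  centers <- rbind(c(4, 8, 8), c(10, 30, 12), c(7, 20, 32), c(11, 9, 35))
  v <- blob_volume(d, centers)
  st <- detectSpots(v)
  expect_identical(nrow(st), nrow(centers))
  m <- oracle_match_spots(as.data.frame(st),
                          data.frame(z = centers[, 1], y = centers[, 2],
                                     x = centers[, 3]), radius = 1)
  expect_identical(unname(m), c(4L, 0L, 0L))
})

test_that("detection count is monotone non-increasing in minPeak", {
  set.seed(32)
  d <- c(10L, 24L, 24L)
  v <- blob_volume(d, rbind(c(5, 8, 8), c(5, 16, 16))) +
    array(rnorm(prod(d), 100, 5), d)
  thresholds <- c(0.5, 2, 10, 50, 1e6)
  n <- vapply(thresholds, function(tp)
    nrow(detectSpots(v, minPeak = tp)), 0L)
  expect_true(all(diff(n) <= 0))
  expect_identical(n[length(n)], 0L)
})

test_that("detectSpots validates arguments and stamps metadata", {
  v <- array(0, c(4, 8, 8))
  expect_error(detectSpots(v, sigma = 0), "sigma")
  v2 <- blob_volume(c(10L, 20L, 20L), rbind(c(5, 10, 10)))
  st <- detectSpots(v2, fov = 3L, round = 2L, channel = 4L)
  expect_identical(st$fov, 3L)
  expect_identical(st$round, 2L)
  expect_identical(st$channel, 4L)
})

test_that("k-means gate separates a planted bimodal mixture", {
  set.seed(33)
  n <- 500
  df <- data.frame(
    spot_id = seq_len(2 * n), fov = 1L, round = 1L, channel = 1L,
    z = 1, y = 1, x = 1,
    intensity = c(rnorm(n, 1000, 100), rnorm(n, 200, 25)))
  truth <- rep(c("signal", "unspecific"), each = n)
  out <- kmeansSignalGate(SpotTable(df))
  mis <- mean(out$class != truth)
  expect_lte(mis, 0.02)
})

test_that("k-means gate equals the exhaustive contiguous-split oracle", {
  set.seed(34)
  for (i in 1:25) {
    n <- sample(2:200, 1)
    x <- switch(1 + i %% 3,
                rnorm(n, 100, 30),
                c(rnorm(ceiling(n / 2), 50, 5), rnorm(floor(n / 2), 500, 50)),
                rlnorm(n, 5, 1))
    x <- pmax(x, 1)
    df <- data.frame(spot_id = seq_len(n), fov = 1L, round = 1L,
                     channel = 1L, z = 1, y = 1, x = 1, intensity = x)
    out <- kmeansSignalGate(SpotTable(df), logIntensity = FALSE)
    expect_identical(out$class == "signal", oracle_split2(x),
                     label = paste("fixture", i))
  }
})

test_that("gate groups are independent per (fov, round, channel)", {
  set.seed(35)
  df <- data.frame(
    spot_id = 1:40, fov = 1L, round = rep(1:2, each = 20), channel = 1L,
    z = 1, y = 1, x = 1,
    # round 1 bimodal; round 2 all high
    intensity = c(rnorm(10, 1000, 10), rnorm(10, 100, 5),
                  rnorm(20, 1000, 10)))
  expect_warning(out <- kmeansSignalGate(SpotTable(df)), NA) # no fallback
  expect_identical(sum(out$class[out$round == 1] == "unspecific"), 10L)
  # round 2 still splits (k-means always partitions into k groups)
  expect_identical(sort(unique(out$class[out$round == 2])),
                   c("signal", "unspecific"))
})

test_that("degenerate gate groups fall back to all-signal with warning", {
  df <- data.frame(spot_id = 1L, fov = 1L, round = 1L, channel = 1L,
                   z = 1, y = 1, x = 1, intensity = 500)
  expect_warning(out <- kmeansSignalGate(SpotTable(df)), "< k")
  expect_identical(out$class, "signal")
  # zero variance
  df2 <- df[rep(1, 5), ]; df2$spot_id <- 1:5
  expect_warning(out2 <- kmeansSignalGate(SpotTable(df2)), "variance")
  expect_true(all(out2$class == "signal"))
  # empty table passes through
  expect_identical(nrow(kmeansSignalGate(SpotTable())), 0L)
})

test_that("codebook construction and decoding follow the layout", {
  cb <- defaultCodebook()
  e <- codebookEntries(cb)
  expect_identical(nrow(e), 30L)
  expect_identical(nRounds(cb), 6L)
  expect_identical(channelsPerRound(cb), 5L)
  expect_identical(e$gene[e$round == 1 & e$channel == 1], "PouV")
  expect_identical(e$gene[e$round == 2 & e$channel == 1], "Foxd3")
  expect_identical(e$gene[e$round == 6 & e$channel == 5], "Epcam")

  df <- data.frame(spot_id = 1:3, fov = 1L, round = c(1L, 2L, 6L),
                   channel = c(1L, 1L, 5L), z = 1, y = 1, x = 1,
                   intensity = 1)
  out <- decodeGene(SpotTable(df), cb)
  expect_identical(out$gene, c("PouV", "Foxd3", "Epcam"))
})

test_that("decode drops reference channels and rejects unknown pairs", {
  cb <- defaultCodebook()
  df <- data.frame(spot_id = 1:2, fov = 1L, round = 1L,
                   channel = c(1L, 6L), z = 1, y = 1, x = 1, intensity = 1)
  expect_message(out <- decodeGene(SpotTable(df), cb,
                                   referenceChannels = 6L),
                 "reference-channel")
  expect_identical(nrow(out), 1L)
  expect_error(decodeGene(SpotTable(df), cb), "7|no codebook entry")
})

test_that("codebook validity rejects collisions and overflow", {
  expect_error(Codebook(c("A", "B"), rounds = c(1, 1), channels = c(1, 1)),
               "at most one gene")
  expect_error(Codebook(c("A", "A"), rounds = c(1, 1), channels = c(1, 2)),
               "exactly once")
  expect_error(Codebook("A", rounds = 3, channels = 1, nRounds = 2),
               "round out of range")
})
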