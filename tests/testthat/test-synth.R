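test_that("simulateSection is deterministic for a fixed seed", {
  cfg <- simPreset("tiny", seed = 7)
  a <- simulateSection(cfg)
  b <- simulateSection(cfg)
  expect_identical(a$stacks, b$stacks)
  expect_identical(as.data.frame(trueSpots(a$truth)),
                   as.data.frame(trueSpots(b$truth)))
  expect_identical(
    SummarizedExperiment::assay(trueCounts(a$truth), "counts"),
    SummarizedExperiment::assay(trueCounts(b$truth), "counts"))
})

test_that("different seeds give different sections", {
  a <- simulateSection(simPreset("tiny", seed = 1))
  b <- simulateSection(simPreset("tiny", seed = 2))
  expect_false(identical(a$stacks, b$stacks))
})

test_that("section shapes follow the config", {
  cfg <- simPreset("tiny", seed = 3)
  sim <- simulateSection(cfg)
  expect_length(sim$stacks, cfg@nFOVs)
  expect_length(sim$stacks[[1]], cfg@nRounds)
  expect_identical(dim(sim$stacks[[1]][[1]]),
                   c(cfg@volumeShape, cfg@channelsPerRound + 2L))
  expect_identical(dim(labelArray(sim$truth@labelVolumes[[1]])),
                   cfg@volumeShape)
})

test_that("true counts conserve rendered signal spots", {
  sim <- simulateSection(simPreset("tiny", seed = 11))
  sp <- as.data.frame(trueSpots(sim$truth))
  cts <- SummarizedExperiment::assay(trueCounts(sim$truth), "counts")
  expect_identical(sum(cts), sum(sp$class == "signal"))
  # and per gene
  per_gene <- table(factor(sp$gene[sp$class == "signal"],
                           levels = rownames(cts)))
  expect_equal(as.integer(per_gene), as.integer(rowSums(cts)))
})

test_that("signal spots lie inside their assigned cell", {
  sim <- simulateSection(simPreset("tiny", seed = 5))
  sp <- as.data.frame(trueSpots(sim$truth))
  sp <- sp[sp$class == "signal", ]
  for (f in unique(sp$fov)) {
    lab <- labelArray(sim$truth@labelVolumes[[f]])
    ss <- sp[sp$fov == f, ]
    got <- lab[cbind(round(ss$z), round(ss$y), round(ss$x))]
    expect_true(all(got == ss$cell_id))
  }
})

test_that("simulateCounts draws NB counts at the programmed means", {
  cfg <- simPreset("default", seed = 21, nCells = 2000L)
  sce <- simulateCounts(cfg)
  cts <- SummarizedExperiment::assay(sce, "counts")
  prog <- SummarizedExperiment::colData(sce)$program
  stem <- cts[, prog == "stem", drop = FALSE]
  n <- ncol(stem)
  expect_gt(n, 300)
  # PouV has mu = 12, size = 8 in the stem program:
  # var = mu + mu^2/size = 30, se(mean) = sqrt(30/n)
  emp <- mean(stem["PouV", ])
  expect_lt(abs(emp - 12), 4 * sqrt(30 / n))
  # basal tier mu = 1 for Krt19 in stem
  emp_lo <- mean(stem["Krt19", ])
  expect_lt(abs(emp_lo - 1), 4 * sqrt((1 + 1 / 8) / n))
})

test_that("program spatial domains are respected", {
  cfg <- simPreset("default", seed = 9, nCells = 300L)
  sce <- simulateCounts(cfg)
  cd <- SummarizedExperiment::colData(sce)
  sect_w <- cfg@nFOVs * cfg@volumeShape[3]
  # global x in voxels: fov offset + local x
  gx <- (cd$fov - 1L) * cfg@volumeShape[3] + cd$centroid_x
  xf <- gx / sect_w
  expect_true(all(xf[cd$program == "neural"] <= 1 / 3 + 0.02))
  expect_true(all(xf[cd$program == "neural_crest"] >= 1 / 3 - 0.02))
  expect_true(all(xf[cd$program == "neural_crest"] <= 2 / 3 + 0.02))
  expect_true(all(xf[cd$program == "epidermal"] >= 2 / 3 - 0.02))
})

test_that("noiseless preset spots honour the minimum separation", {
  sim <- simulateSection(simPreset("noiseless", seed = 13, nFOVs = 1L))
  sp <- as.data.frame(trueSpots(sim$truth))
  sep <- sim$config@minSpotSeparation
  expect_identical(sep, 4L)
  for (g in split(sp, paste(sp$fov, sp$round, sp$channel))) {
    if (nrow(g) < 2) next
    m <- as.matrix(g[, c("z", "y", "x")])
    ch <- pmax(abs(outer(m[, 1], m[, 1], "-")),
               abs(outer(m[, 2], m[, 2], "-")),
               abs(outer(m[, 3], m[, 3], "-")))
    diag(ch) <- Inf
    expect_gte(min(ch), sep - 1)  # jitter is +-0.3 around voxel centres
  }
  # conservation must survive the crowd-drop adjustment
  cts <- SummarizedExperiment::assay(trueCounts(sim$truth), "counts")
  expect_identical(sum(cts), sum(sp$class == "signal"))
})

test_that("planted round shifts are recorded and applied", {
  shifts <- rbind(c(0L, 0L, 0L), c(1L, -2L, 3L))
  cfg <- simPreset("tiny", seed = 4, roundShifts = shifts,
                   noiseSD = 0, backgroundSpotRate = 0, illumAmplitude = 0)
  sim <- simulateSection(cfg)
  applied <- sim$truth@appliedShifts
  dimnames(applied) <- NULL
  expect_identical(applied, shifts)
  # membrane channel of round 2 is the round-1 membrane translated
  cpr <- cfg@channelsPerRound
  m1 <- sim$stacks[[1]][[1]][, , , cpr + 1L]
  m2 <- sim$stacks[[1]][[2]][, , , cpr + 1L]
  expect_equal(applyShift(m1 - cfg@baseline, shifts[2, ]) + cfg@baseline,
               m2, tolerance = 1e-12)
})

test_that("shading field has mean one and bounded deviation", {
  set.seed(1)
  f <- simulateShadingField(64, 80, amplitude = 0.3)
  expect_equal(mean(f), 1, tolerance = 1e-12)
  expect_true(all(f > 0))
  expect_lt(max(abs(f - 1)), 0.35)
  expect_identical(simulateShadingField(10, 10, amplitude = 0),
                   matrix(1, 10, 10))
  expect_error(simulateShadingField(10, 10, amplitude = 1), "amplitude")
})

test_that("constructors validate their inputs", {
  expect_error(SubpopProgram("p", c(a = -1)), "means")
  expect_error(SimConfig(nRounds = 0L))
  expect_error(SimConfig(genePanel = c("A", "A", "B")))
  p <- defaultPrograms()
  expect_length(p, 4)
  expect_setequal(vapply(p, function(x) x@name, ""),
                  c("stem", "neural", "neural_crest", "epidermal"))
})
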