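# a 2-cell label volume and matching codebook used throughout
quant_fixture <- function() {
  lab <- array(0L, c(4, 10, 10))
  lab[, 1:5, 1:5] <- 1L
  lab[, 6:10, 6:10] <- 2L
  lv <- LabelVolume(lab, voxelSize = c(1, 1, 1))
  cb <- Codebook(c("GeneA", "GeneB"), rounds = c(1L, 1L),
                 channels = c(1L, 2L))
  list(lv = lv, cb = cb)
}

spot_row <- function(id, z, y, x, channel = 1L, fov = 1L,
                     class = "signal") {
  data.frame(spot_id = id, fov = fov, round = 1L, channel = channel,
             z = z, y = y, x = x, intensity = 1000, class = class)
}

test_that("spots are assigned to the enclosing cell", {
  fx <- quant_fixture()
  df <- rbind(spot_row(1, 2, 3, 3),     # cell 1
              spot_row(2, 2, 8, 8),     # cell 2
              spot_row(3, 2, 3, 8))     # background (label 0)
  out <- assignSpotsToCells(SpotTable(df), fx$lv)
  expect_identical(out$cell_id, c(1L, 2L, 0L))
})

test_that("fractional coordinates are assigned by rounding", {
  fx <- quant_fixture()
  df <- spot_row(1, 2.4, 4.6, 4.6)      # rounds to (2, 5, 5) -> cell 1
  out <- assignSpotsToCells(SpotTable(df), fx$lv)
  expect_identical(out$cell_id, 1L)
})

test_that("out-of-bounds spots warn and stay unassigned", {
  fx <- quant_fixture()
  df <- spot_row(1, 99, 1, 1)
  expect_warning(out <- assignSpotsToCells(SpotTable(df), fx$lv),
                 "outside")
  expect_identical(out$cell_id, 0L)
})

test_that("buildCountMatrix counts decoded signal spots per cell", {
  fx <- quant_fixture()
  df <- rbind(spot_row(1, 1, 2, 2), spot_row(2, 2, 3, 3),
              spot_row(3, 3, 4, 4),                       # 3x GeneA cell 1
              spot_row(4, 1, 8, 8, channel = 2L),          # 1x GeneB cell 2
              spot_row(5, 2, 8, 9, class = "unspecific"),  # gated out
              spot_row(6, 2, 3, 8))                        # background
  sp <- decodeGene(SpotTable(df), fx$cb)
  sp <- assignSpotsToCells(sp, fx$lv)
  sce <- buildCountMatrix(sp, fx$cb, fx$lv, stage = "HH8")
  m <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(colnames(m), c("1_1", "1_2"))
  expect_identical(unname(m["GeneA", ]), c(3L, 0L))
  expect_identical(unname(m["GeneB", ]), c(0L, 1L))
  cd <- SummarizedExperiment::colData(sce)
  expect_identical(cd$stage, rep("HH8", 2))
  expect_identical(cd$local_id, c(1L, 2L))
})

test_that("cells with zero spots still appear as columns", {
  fx <- quant_fixture()
  sp <- decodeGene(SpotTable(spot_row(1, 1, 2, 2)), fx$cb)
  sp <- assignSpotsToCells(sp, fx$lv)
  sce <- buildCountMatrix(sp, fx$cb, fx$lv)
  expect_identical(ncol(sce), 2L)
  expect_identical(sum(SummarizedExperiment::assay(sce)[, "1_2"]), 0L)
  # and a completely empty spot table gives an all-zero matrix
  sce0 <- buildCountMatrix(SpotTable(), fx$cb, fx$lv)
  expect_identical(dim(SummarizedExperiment::assay(sce0)), c(2L, 2L))
  expect_true(all(SummarizedExperiment::assay(sce0) == 0L))
})

test_that("count matrix is invariant to spot order", {
  fx <- quant_fixture()
  df <- rbind(spot_row(1, 1, 2, 2), spot_row(2, 2, 8, 8, channel = 2L),
              spot_row(3, 3, 4, 4))
  make <- function(d) {
    sp <- assignSpotsToCells(decodeGene(SpotTable(d), fx$cb), fx$lv)
    SummarizedExperiment::assay(buildCountMatrix(sp, fx$cb, fx$lv))
  }
  expect_identical(make(df), make(df[c(3, 1, 2), ]))
})

test_that("undecoded or unknown-gene spots are rejected", {
  fx <- quant_fixture()
  df <- spot_row(1, 1, 2, 2)
  sp <- assignSpotsToCells(SpotTable(df), fx$lv)
  expect_error(buildCountMatrix(sp, fx$cb, fx$lv), "decoded")
  df$gene <- "NotInPanel"
  sp2 <- assignSpotsToCells(SpotTable(df), fx$lv)
  expect_error(buildCountMatrix(sp2, fx$cb, fx$lv), "NotInPanel")
})

test_that("QC filters drop cells by spot count and volume", {
  fx <- quant_fixture()
  df <- rbind(spot_row(1, 1, 2, 2), spot_row(2, 2, 3, 3),
              spot_row(3, 1, 8, 8, channel = 2L))
  sp <- assignSpotsToCells(decodeGene(SpotTable(df), fx$cb), fx$lv)
  sce <- buildCountMatrix(sp, fx$cb, fx$lv, minSpotsPerCell = 2L)
  expect_identical(colnames(sce), "1_1")
  # volume filter: both cells are 100 voxels = 100 um^3 here
  sce2 <- buildCountMatrix(sp, fx$cb, fx$lv, minCellVolume = 101)
  expect_identical(ncol(sce2), 0L)
})

test_that("multi-FOV ids are fov_localid and fovTrim drops overlaps", {
  fx <- quant_fixture()
  lv2 <- fx$lv
  df <- rbind(spot_row(1, 1, 2, 2, fov = 1L),
              spot_row(2, 1, 2, 2, fov = 2L))
  sp <- assignSpotsToCells(decodeGene(SpotTable(df), fx$cb),
                           list(fx$lv, lv2))
  sce <- buildCountMatrix(sp, fx$cb, list(fx$lv, lv2))
  expect_identical(colnames(sce), c("1_1", "1_2", "2_1", "2_2"))
  # trimming the first 60% of FOV >= 2 along x removes cell 2_1
  # (centroid x = 3) but keeps 2_2 (centroid x = 8)
  sce_t <- buildCountMatrix(sp, fx$cb, list(fx$lv, lv2), fovTrim = 0.6)
  expect_identical(colnames(sce_t), c("1_1", "1_2", "2_2"))
})

test_that("noiseless end-to-end counting is exact (single seed)", {
  cfg <- simPreset("noiseless", seed = 101, nFOVs = 1L,
                   volumeShape = c(12L, 60L, 60L), nCells = 8L)
  sim <- simulateSection(cfg)
  truth <- sim$truth
  spl <- list()
  for (r in seq_len(nRounds(cfg))) for (ch in seq_len(channelsPerRound(cfg))) {
    st <- detectSpots(sim$stacks[[1]][[r]][, , , ch], sigma = cfg@spotSigma,
                      voxelSize = cfg@voxelSize, fov = 1L, round = r,
                      channel = ch)
    spl[[length(spl) + 1L]] <- as.data.frame(st)
  }
  det <- do.call(rbind, spl)
  det$class <- "signal"
  sp <- decodeGene(SpotTable(det), sim$codebook)
  labs <- truth@labelVolumes
  cm <- buildCountMatrix(assignSpotsToCells(sp, labs), sim$codebook, labs,
                         stage = "HH8")
  M <- as.matrix(SummarizedExperiment::assay(cm, "counts"))
  colnames(M) <- sub("^1_", "", colnames(M))
  Tm <- as.matrix(SummarizedExperiment::assay(trueCounts(truth), "counts"))
  expect_identical(M[rownames(Tm), colnames(Tm)], Tm)
})
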