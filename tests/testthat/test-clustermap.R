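make_sce <- function(m, stage = rep("HH8", ncol(m))) {
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(stage = stage,
                                   row.names = colnames(m)))
}

test_that("z-scores use the population sd: two cells give -1 and 1", {
  m <- matrix(c(1, 3), 1, 2, dimnames = list("G", c("a", "b")))
  sce <- zscoreCounts(make_sce(m))
  z <- SummarizedExperiment::assay(sce, "zscore")
  expect_equal(unname(z["G", ]), c(-1, 1))
})

test_that("z-score moments are exact per group", {
  set.seed(41)
  m <- matrix(rpois(30 * 200, 6), 30, 200,
              dimnames = list(paste0("g", 1:30), NULL))
  stage <- rep(c("HH8", "HH10"), each = 100)
  sce <- zscoreCounts(make_sce(m, stage), mode = "per_stage")
  z <- SummarizedExperiment::assay(sce, "zscore")
  for (s in unique(stage)) {
    zz <- z[, stage == s, drop = FALSE]
    expect_lt(max(abs(rowMeans(zz))), 1e-9)
    sd_pop <- sqrt(rowMeans((zz - rowMeans(zz))^2))
    expect_lt(max(abs(sd_pop - 1)), 1e-9)
  }
})

test_that("cross_stage mode pools all cells into one group", {
  set.seed(42)
  m <- matrix(rpois(5 * 60, 4), 5, 60,
              dimnames = list(paste0("g", 1:5), NULL))
  stage <- rep(c("HH8", "HH10", "HH12"), each = 20)
  sce <- zscoreCounts(make_sce(m, stage), mode = "cross_stage")
  z <- SummarizedExperiment::assay(sce, "zscore")
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_identical(S4Vectors::metadata(sce)$zscore_mode, "cross_stage")
  expect_identical(
    unname(S4Vectors::metadata(sce)$zscore_grouping), rep("pooled", 60))
})

test_that("zero-variance genes get zero z and are flagged", {
  m <- rbind(G1 = c(5, 5, 5), G2 = c(1, 2, 3))
  sce <- zscoreCounts(make_sce(m))
  z <- SummarizedExperiment::assay(sce, "zscore")
  expect_true(all(z["G1", ] == 0))
  zv <- S4Vectors::metadata(sce)$zero_variance
  expect_true(zv["G1", "HH8"])
  expect_false(zv["G2", "HH8"])
})

test_that("grouping is validated", {
  m <- matrix(1:4, 2, 2)
  expect_error(zscoreCounts(make_sce(m), grouping = "a"), "cover")
  expect_error(zscoreCounts(make_sce(m), grouping = c("a", NA)), "NA")
})

test_that("two planted blobs are recovered as two clusters", {
  set.seed(43)
  z <- cbind(matrix(rnorm(10 * 15, 3), 10),
             matrix(rnorm(10 * 15, -3), 10))
  rownames(z) <- paste0("g", 1:10)
  colnames(z) <- paste0("c", 1:30)
  cl <- hierarchicalCluster(z, k = 2, metric = "euclidean")
  lab <- clusterLabels(cl)
  expect_identical(length(unique(lab[1:15])), 1L)
  expect_identical(length(unique(lab[16:30])), 1L)
  expect_false(lab[1] == lab[16])
  expect_setequal(leafOrder(cl), colnames(z))
})

test_that("merge sequence equals the brute-force agglomerative oracle", {
  set.seed(44)
  for (i in 1:10) {
    m <- matrix(rnorm(4 * 5), 4, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
    for (lk in c("average", "complete")) {
      cl <- hierarchicalCluster(m, k = 2, metric = "euclidean",
                                linkage = lk)
      hc <- cl@hclust
      # reconstruct the member sets merged at each hclust step
      impl <- list()
      members <- list()
      for (s in seq_len(nrow(hc$merge))) {
        get <- function(v) if (v < 0) -v else members[[v]]
        members[[s]] <- sort(c(get(hc$merge[s, 1]), get(hc$merge[s, 2])))
        impl[[s]] <- members[[s]]
      }
      expect_identical(impl, oracle_agglom(m, lk),
                       label = paste("fixture", i, lk))
    }
  }
})

test_that("k bounds and the ward/correlation combination are rejected", {
  m <- matrix(rnorm(20), 4, 5)
  expect_error(hierarchicalCluster(m, k = 0), "between")
  expect_error(hierarchicalCluster(m, k = 6), "between")
  expect_error(hierarchicalCluster(m, k = 2, metric = "correlation",
                                   linkage = "ward"), "euclidean")
  # k = n gives singletons; k = 1 gives one cluster
  expect_identical(sort(unname(clusterLabels(
    hierarchicalCluster(m, k = 5, metric = "euclidean")))), 1:5)
  expect_true(all(clusterLabels(hierarchicalCluster(m, k = 1)) == 1L))
})

test_that("gate keeps exactly the strict all-positive intersection", {
  z <- rbind(A = c(0.5, 0.5, -0.1, 0.0),
             B = c(0.5, 0.5, 0.5, 0.5))
  colnames(z) <- paste0("c", 1:4)
  gr <- gateCoexpression(z, GeneModule("m", c("A", "B")))
  expect_identical(gatedCells(gr), c("c1", "c2"))  # c3 negative, c4 zero
  # single-gene module
  gr1 <- gateCoexpression(z, "A")
  expect_identical(gatedCells(gr1), c("c1", "c2"))
})

test_that("gate equals the brute-force intersection on random fixtures", {
  set.seed(45)
  for (i in 1:100) {
    ng <- sample(3:8, 1); nc <- sample(2:30, 1)
    z <- matrix(rnorm(ng * nc), ng, nc,
                dimnames = list(paste0("g", seq_len(ng)),
                                paste0("c", seq_len(nc))))
    genes <- sample(rownames(z), sample(seq_len(ng), 1))
    gr <- gateCoexpression(z, GeneModule("m", genes))
    expect_identical(gatedCells(gr), oracle_gate(z, genes),
                     label = paste("fixture", i))
  }
})

test_that("adding a gene to a module never grows the gated set", {
  set.seed(46)
  z <- matrix(rnorm(5 * 40), 5, 40,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:40)))
  prev <- colnames(z)
  for (k in 1:5) {
    cur <- gatedCells(gateCoexpression(z, paste0("g", seq_len(k))))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("gate reports per-stage tallies and validates genes", {
  m <- rbind(PouV = c(5, 1, 6, 0), Nanog = c(4, 0, 7, 1),
             Klf4 = c(6, 1, 5, 0))
  sce <- zscoreCounts(make_sce(m, stage = c("HH8", "HH8", "HH10", "HH10")))
  gr <- gateCoexpression(sce, builtinModules("pluripotency"))
  tab <- gr@perStage
  expect_identical(tab$n_cells, c(2L, 2L))
  expect_identical(sum(tab$n_pass), length(gatedCells(gr)))
  expect_error(gateCoexpression(sce, GeneModule("m", c("PouV", "Nope"))),
               "Nope")
  expect_error(GeneModule("m", character()), "at least one")
})

test_that("annotateClusters validates ids and attaches labels", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(NULL, paste0("c", 1:10)))
  cl <- hierarchicalCluster(m, k = 2, metric = "euclidean")
  ann <- annotateClusters(cl, c("1" = "stem", "2" = "neural"),
                          colors = c("1" = "#FF0000"))
  expect_identical(unname(ann@annotations["1"]), "stem")
  expect_identical(unname(ann@colors["1"]), "#FF0000")
  expect_error(annotateClusters(cl, c("9" = "x")), "unknown")
  expect_error(annotateClusters(cl, c("1" = "x")), "missing")
})

test_that("writeHeatmap renders a PNG in leaf order", {
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  cl <- hierarchicalCluster(m, k = 2, metric = "euclidean")
  p <- tempfile(fileext = ".png")
  ord <- writeHeatmap(m, cl, p)
  expect_true(file.exists(p))
  expect_identical(ord, leafOrder(cl))
  expect_gt(file.size(p), 0)
  unlink(p)
})
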