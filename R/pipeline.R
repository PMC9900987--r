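#' Run the full analysis pipeline on a simulated section
#'
#' End-to-end composition of the stages: simulate (or reuse provided
#' stacks), preprocess (flat-field, 3D median, inter-round registration),
#' segment (seeded watershed, or ingest precomputed masks), detect,
#' k-means gate, decode, quantify, z-score + hierarchical cluster,
#' module gates, and back-map rendering. Every artifact is written under
#' \code{outDir} and hashed into \code{manifest.json}; reruns with the
#' same config produce byte-identical artifacts and manifest.
#'
#' @param config nested list of stage settings; see Details. Defaults run
#'   the default simulation preset end to end.
#' @param outDir output directory (created).
#' @details Recognised entries (all optional):
#' \describe{
#'   \item{seed}{integer; master seed, default 1.}
#'   \item{simulate}{list(preset, overrides named list).}
#'   \item{preprocess}{list(kernel, maxShift, flatfield logical).}
#'   \item{segment}{list(enabled, minCellVolume, maskPaths character
#'     vector of per-FOV label TIFFs consumed instead of segmenting).}
#'   \item{detect}{list(sigma, minDistance, minPeak).}
#'   \item{gate}{list(k).}
#'   \item{quantify}{list(minSpotsPerCell, minCellVolume, fovTrim).}
#'   \item{cluster}{list(k, metric, linkage, mode).}
#'   \item{modules}{character vector of built-in module names to gate.}
#' }
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = list(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages_done <- character()
  artifacts <- character()

  # --- simulate -------------------------------------------------------
  simcfg <- do.call(simPreset, c(
    list(name = config$simulate$preset %||% "default", seed = seed),
    config$simulate$overrides %||% list()))
  sim <- simulateSection(simcfg)
  cb <- sim$codebook
  truth <- sim$truth
  n_fov <- simcfg@nFOVs
  cpr <- simcfg@channelsPerRound
  n_chan <- cpr + 2L
  stages_done <- c(stages_done, "simulate")

  jsonlite::write_json(list(seed = seed,
                            preset = config$simulate$preset %||% "default",
                            volumeShape = simcfg@volumeShape,
                            nRounds = simcfg@nRounds,
                            channelsPerRound = cpr,
                            nFOVs = n_fov,
                            nCells = simcfg@nCells,
                            genePanel = simcfg@genePanel),
                       file.path(outDir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  artifacts <- c(artifacts, "config.json")

  # --- preprocess -----------------------------------------------------
  pp <- config$preprocess %||% list()
  kernel <- pp$kernel %||% 3L
  max_shift <- pp$maxShift %||% pmin(c(2L, 8L, 8L),
                                     (simcfg@volumeShape - 1L) %/% 2L)
  use_ff <- pp$flatfield %||% TRUE
  flatfields <- NULL
  if (use_ff) {
    flatfields <- lapply(seq_len(n_chan), function(ch) {
      planes <- list()
      for (f in seq_len(n_fov))
        for (r in seq_len(simcfg@nRounds)) {
          v <- sim$stacks[[f]][[r]][, , , ch]
          for (z in seq_len(dim(v)[1]))
            planes[[length(planes) + 1L]] <-
              matrix(v[z, , ], dim(v)[2], dim(v)[3])
        }
      estimateFlatfield(planes)
    })
  }
  shifts_tab <- list()
  pre <- vector("list", n_fov)
  for (f in seq_len(n_fov)) {
    rounds <- vector("list", simcfg@nRounds)
    ref <- NULL
    for (r in seq_len(simcfg@nRounds)) {
      res <- preprocessStack(sim$stacks[[f]][[r]], flatfields,
                             reference = ref,
                             registrationChannel = cpr + 1L,
                             kernel = kernel, maxShift = max_shift)
      if (r == 1L) ref <- res$stack[, , , cpr + 1L]
      rounds[[r]] <- res$stack
      shifts_tab[[length(shifts_tab) + 1L]] <- data.frame(
        fov = f, round = r, dz = res$shift[1], dy = res$shift[2],
        dx = res$shift[3], score = res$score)
    }
    pre[[f]] <- rounds
  }
  writeShiftTable(do.call(rbind, shifts_tab), file.path(outDir, "shifts.csv"))
  artifacts <- c(artifacts, "shifts.csv")
  stages_done <- c(stages_done, "preprocess")

  # --- segment --------------------------------------------------------
  seg <- config$segment %||% list()
  labels <- vector("list", n_fov)
  if (!is.null(seg$maskPaths)) {
    for (f in seq_len(n_fov))
      labels[[f]] <- loadLabels(seg$maskPaths[[f]], simcfg@voxelSize)
  } else if (isFALSE(seg$enabled)) {
    stop("segmentation disabled but no maskPaths provided; ",
         "run the segment stage or supply masks", call. = FALSE)
  } else {
    for (f in seq_len(n_fov))
      labels[[f]] <- segmentCells(pre[[f]][[1L]][, , , cpr + 1L],
                                  pre[[f]][[1L]][, , , cpr + 2L],
                                  voxelSize = simcfg@voxelSize,
                                  minCellVolume = seg$minCellVolume %||% 10)
  }
  for (f in seq_len(n_fov))
    writeLabels(labels[[f]], file.path(outDir, sprintf("labels_fov%d.tif", f)))
  artifacts <- c(artifacts, sprintf("labels_fov%d.tif", seq_len(n_fov)))
  stages_done <- c(stages_done, "segment")

  # --- detect ---------------------------------------------------------
  det <- config$detect %||% list()
  spot_parts <- list()
  for (f in seq_len(n_fov))
    for (r in seq_len(simcfg@nRounds))
      for (ch in seq_len(cpr)) {
        st <- detectSpots(pre[[f]][[r]][, , , ch],
                          sigma = det$sigma %||% simcfg@spotSigma,
                          voxelSize = simcfg@voxelSize,
                          minDistance = det$minDistance %||% 1L,
                          minPeak = det$minPeak,
                          fov = f, round = r, channel = ch)
        spot_parts[[length(spot_parts) + 1L]] <- .spot_df(st)
      }
  spots <- SpotTable(do.call(rbind, spot_parts))
  spots_df <- .spot_df(spots)
  spots_df$spot_id <- seq_len(nrow(spots_df))
  spots <- SpotTable(spots_df)
  stages_done <- c(stages_done, "detect")

  # --- gate + decode --------------------------------------------------
  spots <- kmeansSignalGate(spots, k = config$gate$k %||% 2L)
  spots <- decodeGene(spots, cb)
  stages_done <- c(stages_done, "gate", "decode")

  # --- quantify -------------------------------------------------------
  qf <- config$quantify %||% list()
  spots <- assignSpotsToCells(spots, labels)
  writeSpotTable(spots, file.path(outDir, "spots.csv"))
  artifacts <- c(artifacts, "spots.csv")
  sce <- buildCountMatrix(spots, cb, labels,
                          minSpotsPerCell = qf$minSpotsPerCell %||% 0L,
                          minCellVolume = qf$minCellVolume %||% 0,
                          stage = simcfg@stage,
                          fovTrim = qf$fovTrim %||% 0)
  writeCountsMTX(sce, file.path(outDir, "counts"))
  artifacts <- c(artifacts, file.path("counts", c("counts.mtx", "genes.csv",
                                                  "cells.csv")))
  stages_done <- c(stages_done, "quantify")

  # --- cluster + modules ----------------------------------------------
  cl <- config$cluster %||% list()
  assignment <- NULL
  if (ncol(sce) >= 2L) {
    sce <- zscoreCounts(sce, mode = cl$mode %||% "per_stage")
    k <- min(cl$k %||% length(simcfg@programs), ncol(sce))
    assignment <- hierarchicalCluster(sce, k = k,
                                      metric = cl$metric %||% "correlation",
                                      linkage = cl$linkage %||% "average")
    utils::write.csv(data.frame(
      cell_id = names(clusterLabels(assignment)),
      cluster = as.integer(clusterLabels(assignment)),
      color = assignment@colors[as.character(clusterLabels(assignment))],
      annotation = assignment@annotations[as.character(clusterLabels(assignment))],
      row.names = NULL),
      file.path(outDir, "clusters.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "clusters.csv")
    writeHeatmap(sce, assignment, file.path(outDir, "heatmap.png"))
    artifacts <- c(artifacts, "heatmap.png")

    mods <- config$modules %||% c("pluripotency", "pan_ectoderm")
    gate_summ <- list()
    for (mn in mods) {
      gr <- gateCoexpression(sce, builtinModules(mn))
      gate_summ[[mn]] <- list(n_pass = length(gatedCells(gr)),
                              cells = gatedCells(gr),
                              per_stage = gr@perStage)
    }
    jsonlite::write_json(gate_summ, file.path(outDir, "gates.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    artifacts <- c(artifacts, "gates.json")
    stages_done <- c(stages_done, "cluster", "gate_modules")

    # --- render -------------------------------------------------------
    for (f in seq_len(n_fov)) {
      img <- backmap(labels[[f]], cellColoring(assignment, fov = f))
      writeBackmap(img, file.path(outDir, sprintf("backmap_fov%d.png", f)))
    }
    artifacts <- c(artifacts,
                   sprintf("backmap_fov%d.png", seq_len(n_fov)),
                   sprintf("backmap_fov%d.png.legend.json", seq_len(n_fov)))
    stages_done <- c(stages_done, "render")
  }

  manifest <- list(
    package = "MuxFISH",
    version = as.character(utils::packageVersion("MuxFISH")),
    seed = seed,
    stages = stages_done,
    files = lapply(stats::setNames(artifacts, artifacts), function(a)
      unname(tools::md5sum(file.path(outDir, a)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
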