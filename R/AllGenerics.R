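#' @include AllClasses.R
NULL

#' Accessors for MuxFISH classes
#'
#' Small generic accessors: \code{genePanel} returns the ordered gene
#' names of a codebook or config; \code{codebookEntries} the
#' (round, channel, gene) table; \code{labelArray} the raw 3D integer
#' array of a \linkS4class{LabelVolume}; \code{voxelSize} the micrometre
#' voxel pitch; \code{cellIds} the positive labels present;
#' \code{cellCentroids} per-cell (z, y, x) centroids in voxel units;
#' \code{cellVolumes} per-cell volumes in cubic micrometres;
#' \code{clusterLabels} the named flat cluster vector;
#' \code{leafOrder} the dendrogram display order;
#' \code{gatedCells} the passing cell ids of a gate;
#' \code{moduleGenes} the gene set of a module;
#' \code{trueSpots} / \code{trueCounts} the simulator's ground truth.
#'
#' @param x an object of the documented class.
#' @return see the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genePanel", function(x) standardGeneric("genePanel"))
#' @rdname accessors
#' @export
setGeneric("codebookEntries", function(x) standardGeneric("codebookEntries"))
#' @rdname accessors
#' @export
setGeneric("nRounds", function(x) standardGeneric("nRounds"))
#' @rdname accessors
#' @export
setGeneric("channelsPerRound", function(x) standardGeneric("channelsPerRound"))
#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("cellCentroids", function(x) standardGeneric("cellCentroids"))
#' @rdname accessors
#' @export
setGeneric("cellVolumes", function(x) standardGeneric("cellVolumes"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))
#' @rdname accessors
#' @export
setGeneric("gatedCells", function(x) standardGeneric("gatedCells"))
#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))
#' @rdname accessors
#' @export
setGeneric("trueSpots", function(x) standardGeneric("trueSpots"))
#' @rdname accessors
#' @export
setGeneric("trueCounts", function(x) standardGeneric("trueCounts"))

#' @rdname accessors
#' @export
setMethod("genePanel", "Codebook", function(x) x@entries$gene)
#' @rdname accessors
#' @export
setMethod("genePanel", "SimConfig", function(x) x@genePanel)
#' @rdname accessors
#' @export
setMethod("codebookEntries", "Codebook", function(x) x@entries)
#' @rdname accessors
#' @export
setMethod("nRounds", "Codebook", function(x) x@nRounds)
#' @rdname accessors
#' @export
setMethod("nRounds", "SimConfig", function(x) x@nRounds)
#' @rdname accessors
#' @export
setMethod("channelsPerRound", "Codebook", function(x) x@channelsPerRound)
#' @rdname accessors
#' @export
setMethod("channelsPerRound", "SimConfig", function(x) x@channelsPerRound)
#' @rdname accessors
#' @export
setMethod("labelArray", "LabelVolume", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("cellIds", "LabelVolume", function(x) {
  ids <- sort(unique(as.vector(x@labels)))
  ids[ids > 0L]
})
#' @rdname accessors
#' @export
setMethod("cellCentroids", "LabelVolume", function(x) {
  lab <- x@labels
  pos <- which(lab > 0L)
  if (!length(pos))
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  d <- dim(lab)
  ids <- lab[pos]
  z <- ((pos - 1L) %% d[1]) + 1L
  y <- (((pos - 1L) %/% d[1]) %% d[2]) + 1L
  xx <- ((pos - 1L) %/% (d[1] * d[2])) + 1L
  cz <- tapply(z, ids, mean)
  cy <- tapply(y, ids, mean)
  cx <- tapply(xx, ids, mean)
  out <- cbind(z = as.numeric(cz), y = as.numeric(cy), x = as.numeric(cx))
  rownames(out) <- names(cz)
  out
})
#' @rdname accessors
#' @export
setMethod("cellVolumes", "LabelVolume", function(x) {
  lab <- x@labels
  tab <- table(lab[lab > 0L])
  vv <- as.numeric(tab) * prod(x@voxelSize)
  names(vv) <- names(tab)
  vv
})
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@cluster)
#' @rdname accessors
#' @export
setMethod("leafOrder", "ClusterAssignment", function(x) x@leafOrder)
#' @rdname accessors
#' @export
setMethod("gatedCells", "GateResult", function(x) x@cellIds)
#' @rdname accessors
#' @export
setMethod("moduleGenes", "GeneModule", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("trueSpots", "GroundTruth", function(x) x@trueSpots)
#' @rdname accessors
#' @export
setMethod("trueCounts", "GroundTruth", function(x) x@trueCounts)

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook: %d genes over %d rounds x %d channels\n",
              nrow(object@entries), object@nRounds, object@channelsPerRound))
  if (nrow(object@entries)) {
    g <- object@entries$gene
    cat("  genes:", paste(utils::head(g, 8), collapse = ", "),
        if (length(g) > 8) sprintf("... (%d total)", length(g)) else "", "\n")
  }
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelVolume: %d x %d x %d voxels (z,y,x), %d cells\n",
              d[1], d[2], d[3], length(cellIds(object))))
  cat(sprintf("  voxel size: %.3g x %.3g x %.3g um\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "SpotTable", function(object) {
  cat(sprintf("SpotTable: %d spots\n", nrow(object)))
  if ("class" %in% colnames(object) && nrow(object)) {
    tt <- table(object$class, useNA = "ifany")
    cat("  class:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  }
  if ("gene" %in% colnames(object) && nrow(object))
    cat(sprintf("  %d distinct genes\n", length(unique(object$gene))))
  callNextMethod()
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d FOV(s) of %s voxels, %d cells, %d genes over ",
    "%d rounds x %d channels\n"),
    object@nFOVs, paste(object@volumeShape, collapse = "x"),
    object@nCells, length(object@genePanel),
    object@nRounds, object@channelsPerRound))
  cat(sprintf("  signal %g+-%g vs background %g+-%g a.u., noise sd %g\n",
              object@signalIntensity[1], object@signalIntensity[2],
              object@backgroundIntensity[1], object@backgroundIntensity[2],
              object@noiseSD))
  cat(sprintf("  programs: %s; seed %d\n",
              paste(vapply(object@programs, function(p) p@name, ""),
                    collapse = ", "), object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d FOV(s), %d true spots, %d x %d counts\n",
              length(object@labelVolumes), nrow(object@trueSpots),
              nrow(object@trueCounts), ncol(object@trueCounts)))
})

setMethod("show", "GeneModule", function(object) {
  cat(sprintf("GeneModule '%s': %s\n", object@name,
              paste(object@genes, collapse = ", ")))
})

setMethod("show", "ClusterAssignment", function(object) {
  tt <- table(object@cluster)
  cat(sprintf("ClusterAssignment: %d cells in %d clusters (%s/%s)\n",
              length(object@cluster), length(tt),
              object@params$metric %||% "?", object@params$linkage %||% "?"))
  cat("  sizes:", paste(names(tt), tt, sep = ":", collapse = " "), "\n")
})

setMethod("show", "GateResult", function(object) {
  cat(sprintf("GateResult '%s' (%s): %d cells pass\n",
              object@module@name,
              paste(object@module@genes, collapse = "+"),
              length(object@cellIds)))
})
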