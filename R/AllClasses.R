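#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' Codebook: the (round, channel) to gene lookup
#'
#' Sequential multiplexed smFISH reads out one gene per (hybridisation
#' round, imaging channel) pair; the codebook is the injective map from
#' those pairs to gene names and defines the panel and its order.
#'
#' @slot entries data.frame with columns \code{round}, \code{channel},
#'   \code{gene}; one row per panel gene.
#' @slot nRounds number of hybridisation rounds.
#' @slot channelsPerRound number of readout channels per round (reference
#'   channels such as DAPI or membrane are not codebook entries).
#' @export
setClass("Codebook",
  representation(entries = "data.frame",
                 nRounds = "integer",
                 channelsPerRound = "integer"))

setValidity("Codebook", function(object) {
  e <- object@entries
  msg <- character()
  req <- c("round", "channel", "gene")
  if (!all(req %in% names(e)))
    return(paste("entries must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(e$gene))
    msg <- c(msg, "each gene must appear exactly once")
  if (anyDuplicated(e[, c("round", "channel")]))
    msg <- c(msg, "each (round, channel) pair may carry at most one gene")
  if (nrow(e) > object@nRounds * object@channelsPerRound)
    msg <- c(msg, "more entries than round x channel capacity")
  if (any(e$round < 1L | e$round > object@nRounds))
    msg <- c(msg, "round out of range")
  if (any(e$channel < 1L | e$channel > object@channelsPerRound))
    msg <- c(msg, "channel out of range")
  if (length(msg)) msg else TRUE
})

#' Retrospective flat-field model
#'
#' Multiplicative shading field (spatial mean 1) plus an optional additive
#' dark-field offset, as estimated from a collection of planes of one
#' channel.
#'
#' @slot flatfield strictly positive 2D matrix (y, x), spatial mean 1.
#' @slot darkfield additive offset image, all entries >= 0.
#' @export
setClass("FlatField",
  representation(flatfield = "matrix", darkfield = "matrix"))

setValidity("FlatField", function(object) {
  msg <- character()
  if (any(object@flatfield <= 0))
    msg <- c(msg, "flatfield must be strictly positive everywhere")
  if (abs(mean(object@flatfield) - 1) > 1e-6)
    msg <- c(msg, "flatfield must be normalised to spatial mean 1")
  if (any(object@darkfield < 0))
    msg <- c(msg, "darkfield must be non-negative")
  if (length(msg)) msg else TRUE
})

#' 3D cell-label volume
#'
#' Integer volume in (z, y, x) order; 0 is background, positive values are
#' cell ids. The product of segmentation and the canvas for back-mapping.
#'
#' @slot labels 3D integer array, dim (nz, ny, nx).
#' @slot voxelSize numeric(3), micrometres per voxel along (z, y, x).
#' @export
setClass("LabelVolume",
  representation(labels = "array", voxelSize = "numeric"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (!is.integer(object@labels))
    msg <- c(msg, "labels must be an integer array")
  else if (any(object@labels < 0L))
    msg <- c(msg, "labels must be non-negative (0 = background)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive values (z, y, x)")
  if (length(msg)) msg else TRUE
})

#' Spot table
#'
#' One record per detected (or simulated) RNA spot. Extends
#' \linkS4class{DFrame}; required columns are \code{spot_id}, \code{fov},
#' \code{round}, \code{channel}, \code{z}, \code{y}, \code{x} (1-based
#' voxel indices) and \code{intensity}. The columns \code{gene} (after
#' decoding), \code{class} ("signal"/"unspecific", after gating) and
#' \code{cell_id} (0 = unassigned, after cell assignment) are added by the
#' corresponding pipeline stages.
#'
#' @export
setClass("SpotTable", contains = "DFrame")

.spot_required <- c("spot_id", "fov", "round", "channel",
                    "z", "y", "x", "intensity")

setValidity("SpotTable", function(object) {
  miss <- setdiff(.spot_required, colnames(object))
  if (length(miss))
    return(paste("missing required spot column(s):",
                 paste(miss, collapse = ", ")))
  if (nrow(object) && "class" %in% colnames(object)) {
    cl <- object$class
    if (!all(is.na(cl) | cl %in% c("signal", "unspecific")))
      return("class must be 'signal' or 'unspecific' (or NA before gating)")
  }
  TRUE
})

#' Subpopulation expression program
#'
#' A named transcriptional program used by the simulator: per-gene
#' negative-binomial means, a shared NB size (inverse-dispersion) and the
#' spatial band of the section footprint where member cells sit.
#'
#' @slot name program name.
#' @slot color display colour.
#' @slot domain numeric(2), fractional range along the section's
#'   medio-lateral (x) axis where member cells are placed; c(0, 1) spans
#'   the full width.
#' @slot means named numeric, NB mean per panel gene.
#' @slot dispersion NB size parameter theta (variance = mu + mu^2 / theta).
#' @export
setClass("SubpopProgram",
  representation(name = "character", color = "character",
                 domain = "numeric", means = "numeric",
                 dispersion = "numeric"))

setValidity("SubpopProgram", function(object) {
  msg <- character()
  if (any(object@means < 0)) msg <- c(msg, "all gene means must be >= 0")
  if (is.null(names(object@means)) || any(!nzchar(names(object@means))))
    msg <- c(msg, "means must be named by gene")
  if (length(object@domain) != 2L || object@domain[1] > object@domain[2] ||
      object@domain[1] < 0 || object@domain[2] > 1)
    msg <- c(msg, "domain must be an increasing pair within [0, 1]")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be positive")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Acquisition geometry, optics, panel, expression programs and noise
#' settings for the synthetic multi-round smFISH generator. See
#' \code{\link{SimConfig}} for defaults and units.
#'
#' @export
setClass("SimConfig",
  representation(volumeShape = "integer",       # (nz, ny, nx) per FOV
                 voxelSize = "numeric",         # um per axis (z, y, x)
                 nRounds = "integer",
                 channelsPerRound = "integer",
                 genePanel = "character",
                 nFOVs = "integer",
                 nCells = "integer",            # total across FOVs
                 programs = "list",
                 backgroundSpotRate = "numeric",# spots per 1000 um^3 per channel
                 spotSigma = "numeric",         # um, isotropic
                 signalIntensity = "numeric",   # (mean, sd), a.u.
                 backgroundIntensity = "numeric",
                 baseline = "numeric",          # camera offset, a.u.
                 illumAmplitude = "numeric",    # peak fractional shading
                 driftMax = "integer",          # (z, y, x) max |round shift|
                 roundShifts = "ANY",           # matrix or NULL (drawn)
                 noiseSD = "numeric",
                 minSpotSeparation = "integer", # Chebyshev voxels, 0 = off
                 stage = "character",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@volumeShape) != 3L || any(object@volumeShape < 1L))
    msg <- c(msg, "volumeShape must be three positive integers (z, y, x)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive values")
  if (object@nRounds < 1L || object@channelsPerRound < 1L)
    msg <- c(msg, "nRounds and channelsPerRound must be >= 1")
  if (length(object@genePanel) >
      object@nRounds * object@channelsPerRound)
    msg <- c(msg, "gene panel exceeds round x channel capacity")
  if (anyDuplicated(object@genePanel))
    msg <- c(msg, "gene panel contains duplicates")
  if (object@nFOVs < 1L) msg <- c(msg, "nFOVs must be >= 1")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (object@signalIntensity[1] <= object@backgroundIntensity[1])
    msg <- c(msg, "signal mean intensity must exceed background mean")
  if (any(object@driftMax > object@volumeShape %/% 4L))
    msg <- c(msg, "round shifts must stay within volumeShape / 4")
  if (!is.null(object@roundShifts)) {
    rs <- object@roundShifts
    if (!is.matrix(rs) || nrow(rs) != object@nRounds || ncol(rs) != 3L)
      msg <- c(msg, "roundShifts must be an nRounds x 3 matrix or NULL")
    else if (any(abs(rs) > matrix(object@volumeShape %/% 4L,
                                  nrow(rs), 3, byrow = TRUE)))
      msg <- c(msg, "roundShifts must stay within volumeShape / 4")
  }
  for (p in object@programs) {
    if (!is(p, "SubpopProgram")) {
      msg <- c(msg, "programs must be SubpopProgram objects"); break
    }
    if (!all(object@genePanel %in% names(p@means))) {
      msg <- c(msg, sprintf(
        "program '%s' lacks a mean for some panel gene", p@name)); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Simulation ground truth
#'
#' Everything the generator knows about a synthetic section: the true cell
#' labels per FOV, every rendered spot with its true gene, class and cell,
#' the exact gene x cell count matrix, the program each cell was drawn
#' from, and the applied round shifts and shading fields.
#'
#' @slot labelVolumes list of \linkS4class{LabelVolume}, one per FOV.
#' @slot trueSpots \linkS4class{SpotTable} with \code{gene}, \code{class}
#'   and \code{cell_id} filled in (coordinates in the unshifted frame).
#' @slot trueCounts \linkS4class{SingleCellExperiment}; assay
#'   \code{"counts"}, colData carries fov, stage, program and centroid.
#' @slot cellSubpop named character, cell id -> program name.
#' @slot appliedShifts nRounds x 3 integer matrix of (dz, dy, dx).
#' @slot appliedFlatfields list of per-channel 2D shading fields.
#' @export
setClass("GroundTruth",
  representation(labelVolumes = "list",
                 trueSpots = "SpotTable",
                 trueCounts = "SingleCellExperiment",
                 cellSubpop = "character",
                 appliedShifts = "matrix",
                 appliedFlatfields = "list"))

#' Gene module
#'
#' A named subset of the panel used for strict z > 0 co-expression gating
#' (for example the pluripotency trio PouV/Oct4 + Nanog + Klf4).
#'
#' @slot name module name.
#' @slot genes character vector of panel genes.
#' @export
setClass("GeneModule",
  representation(name = "character", genes = "character"))

setValidity("GeneModule", function(object) {
  if (!length(object@genes)) return("module must contain at least one gene")
  if (anyDuplicated(object@genes)) return("module genes must be unique")
  TRUE
})

#' Cluster assignment
#'
#' Flat subpopulation labels for every cell together with the dendrogram
#' they were cut from, the heatmap leaf order, and per-cluster display
#' colours and free-text annotations.
#'
#' @slot cluster named integer, cell id -> cluster id.
#' @slot hclust the \code{stats::hclust} linkage object.
#' @slot leafOrder cell ids in dendrogram leaf (display) order.
#' @slot colors named character, cluster id -> colour.
#' @slot annotations named character, cluster id -> label.
#' @slot params list: metric, linkage, k.
#' @export
setClass("ClusterAssignment",
  representation(cluster = "integer", hclust = "ANY",
                 leafOrder = "character", colors = "character",
                 annotations = "character", params = "list"))

setValidity("ClusterAssignment", function(object) {
  if (is.null(names(object@cluster)))
    return("cluster must be named by cell id")
  if (!setequal(names(object@cluster), object@leafOrder))
    return("leafOrder must contain exactly the clustered cells")
  TRUE
})

#' Co-expression gate result
#'
#' The set of cells whose z-score is strictly positive for every gene of a
#' module, with per-stage tallies.
#'
#' @slot module the \linkS4class{GeneModule} that was gated.
#' @slot cellIds character vector of passing cell ids.
#' @slot perStage data.frame: stage, n_cells, n_pass, fraction.
#' @export
setClass("GateResult",
  representation(module = "GeneModule", cellIds = "character",
                 perStage = "data.frame"))
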