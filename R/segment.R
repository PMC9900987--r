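#' Construct a LabelVolume
#'
#' @param labels 3D non-negative integer array (z, y, x).
#' @param voxelSize numeric(3), um per voxel (z, y, x).
#' @return a validated \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(labels, voxelSize = c(0.5, 0.21, 0.21)) {
  if (!is.integer(labels)) {
    if (any(labels != round(labels)))
      stop("labels must be integer-valued", call. = FALSE)
    storage.mode(labels) <- "integer"
  }
  new("LabelVolume", labels = labels, voxelSize = as.numeric(voxelSize))
}

#' Seeded 3D watershed cell segmentation
#'
#' Classical stand-in for learned 3D segmentation: nuclear seeds are the
#' local maxima of the Gaussian-smoothed nuclei (DAPI) channel, the
#' foreground mask is an Otsu threshold of the smoothed combined signal,
#' and cells grow from the seeds by ordered flooding of the membrane
#' intensity (6-connectivity), so cell boundaries settle on membrane
#' ridges. Cells smaller than \code{minCellVolume} are discarded (their
#' voxels revert to background). Labels are relabelled 1..K ordered by
#' seed centroid (z, y, x).
#'
#' @param membrane,nuclei preprocessed 3D arrays of identical shape.
#' @param voxelSize numeric(3), um per voxel.
#' @param minCellVolume minimum cell volume in um^3 (default 10).
#' @param nucleusSigma smoothing sigma for seed detection, um.
#' @param seedMinDistance minimum seed separation, um.
#' @param mask optional logical foreground volume; default is an Otsu
#'   threshold of smoothed(membrane + nuclei), or the full volume when
#'   thresholding separates nothing.
#' @return a \linkS4class{LabelVolume}; empty (all background, with a
#'   warning) when no seeds are found.
#' @export
segmentCells <- function(membrane, nuclei, voxelSize = c(0.5, 0.21, 0.21),
                         minCellVolume = 10, nucleusSigma = 1.0,
                         seedMinDistance = 2.5, mask = NULL) {
  .check_volume(membrane, "membrane")
  .check_volume(nuclei, "nuclei")
  if (!identical(dim(membrane), dim(nuclei)))
    stop("membrane and nuclei must have identical shapes", call. = FALSE)
  d <- dim(membrane)
  sig_vox <- nucleusSigma / voxelSize
  sm_nuc <- .gauss3d(nuclei, sig_vox)

  if (is.null(mask)) {
    comb <- .gauss3d(membrane + nuclei, sig_vox)
    thr <- .otsu(comb)
    mask <- comb > thr
    # degenerate: essentially everything (or nothing) foreground
    if (mean(mask) > 0.95 || mean(mask) < 0.01)
      mask <- array(TRUE, d)
  }

  rad <- pmax(1L, as.integer(round(seedMinDistance / voxelSize)))
  # Otsu on the smoothed nuclei separates nuclear from background intensity
  # regardless of how much of the volume the nuclei occupy
  floor_int <- .otsu(sm_nuc)
  peaks <- cpp_local_max(sm_nuc, d, rad[1], rad[2], rad[3], floor_int)
  peaks <- peaks[mask[peaks]]
  if (!length(peaks)) {
    warning("no nuclear seeds found; returning an empty LabelVolume")
    return(LabelVolume(array(0L, d), voxelSize))
  }
  zyx <- .ind2zyx(peaks, d)
  ord <- order(zyx[, 1], zyx[, 2], zyx[, 3])
  peaks <- peaks[ord]

  seeds <- array(0L, d)
  seeds[peaks] <- seq_along(peaks)
  lab <- cpp_seeded_watershed(as.numeric(membrane), d, seeds,
                              as.logical(mask))
  lab <- array(as.integer(lab), d)

  # volume filter + deterministic relabel by seed order (already sorted)
  sizes <- tabulate(lab[lab > 0L], nbins = length(peaks))
  keep <- which(sizes * prod(voxelSize) >= minCellVolume)
  remap <- integer(length(peaks))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  LabelVolume(lab, voxelSize)
}

# Otsu threshold on a 256-bin histogram
.otsu <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(255L, as.integer((x - rng[1]) / diff(rng) * 256)) + 1L,
                nbins = 256L)
  w <- cumsum(h)
  m <- cumsum(h * (seq_len(256) - 1))
  mt <- m[256]
  n <- w[256]
  between <- (mt * w - m * n)^2 / (w * (n - w))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  rng[1] + (k - 0.5) / 256 * diff(rng)
}

#' Validate and load a label volume
#'
#' Builds a \linkS4class{LabelVolume} from a raw integer array or a TIFF
#' file written by \code{\link{writeLabels}}. With \code{strict = TRUE},
#' every positive label must form a single 26-connected component; the
#' error names all offending labels.
#'
#' @param x path to an integer TIFF volume, or a 3D integer array.
#' @param voxelSize numeric(3) um per voxel.
#' @param minCellVolume discard cells smaller than this many um^3
#'   (default 0 = keep all).
#' @param strict enforce one connected component per label.
#' @return a \linkS4class{LabelVolume}.
#' @export
loadLabels <- function(x, voxelSize = c(0.5, 0.21, 0.21),
                       minCellVolume = 0, strict = FALSE) {
  if (is.character(x)) x <- readVolumeTIFF(x, integer = TRUE)
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("labels must be a 3D array", call. = FALSE)
  if (any(x != round(x)))
    stop("label volume contains non-integer values", call. = FALSE)
  if (any(x < 0))
    stop("label volume contains negative values", call. = FALSE)
  storage.mode(x) <- "integer"
  if (minCellVolume > 0) {
    tab <- table(x[x > 0L])
    bad <- as.integer(names(tab)[as.numeric(tab) * prod(voxelSize) <
                                   minCellVolume])
    if (length(bad)) x[x %in% bad] <- 0L
  }
  if (strict) {
    comp <- cpp_label_components(x, dim(x), 26L)
    ncomp <- tapply(comp[x > 0L], x[x > 0L],
                    function(v) length(unique(v)))
    bad <- names(ncomp)[ncomp > 1L]
    if (length(bad))
      stop("label(s) with multiple connected components: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  LabelVolume(x, voxelSize)
}
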