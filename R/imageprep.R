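#' Retrospective flat-field estimation
#'
#' Estimates the smooth multiplicative shading of one channel from a
#' collection of planes, without any calibration image: the per-pixel
#' median across planes cancels the (plane-varying) content and retains
#' the (fixed) shading, which is then smoothed with a wide Gaussian and
#' normalised to spatial mean 1. Dark-field estimation (per-pixel minimum,
#' smoothed) is optional and off by default.
#'
#' @param planes a list of equally sized 2D matrices, or a 3D array with
#'   planes stacked along the third dimension; at least 2 planes (8 or
#'   more recommended).
#' @param smoothSigma Gaussian sigma in pixels for the smoothing step;
#'   default one eighth of the smaller image dimension.
#' @param darkfield estimate an additive dark-field too (default FALSE,
#'   giving a zero dark-field).
#' @return a \linkS4class{FlatField}.
#' @export
estimateFlatfield <- function(planes, smoothSigma = NULL,
                              darkfield = FALSE) {
  if (is.array(planes) && length(dim(planes)) == 3L)
    planes <- lapply(seq_len(dim(planes)[3]), function(i) planes[, , i])
  if (!is.list(planes) || length(planes) < 2L)
    stop("flat-field estimation needs at least 2 planes", call. = FALSE)
  dm <- dim(planes[[1]])
  if (!all(vapply(planes, function(p) identical(dim(p), dm), TRUE)))
    stop("all planes must have identical dimensions", call. = FALSE)
  if (length(planes) < 8L)
    warning("fewer than 8 planes; flat-field estimate may be unstable")
  sigma <- smoothSigma %||% (min(dm) / 8)
  stk <- array(unlist(planes), c(dm, length(planes)))
  med <- apply(stk, c(1, 2), stats::median)
  sm <- .smooth2d(med, sigma)
  sm <- pmax(sm, 1e-6 * max(sm))
  ff <- sm / mean(sm)
  df <- matrix(0, dm[1], dm[2])
  if (darkfield) {
    mn <- apply(stk, c(1, 2), min)
    df <- pmax(.smooth2d(mn, sigma), 0)
  }
  new("FlatField", flatfield = ff, darkfield = df)
}

# 2D Gaussian smoothing via the 3D separable kernel with a singleton z
.smooth2d <- function(m, sigma) {
  v <- array(m, c(1L, dim(m)))
  v <- .gauss3d(v, c(0, sigma, sigma))
  matrix(v, dim(m)[1], dim(m)[2])
}

#' Apply a flat-field correction
#'
#' Computes \code{(input - darkfield) / flatfield}, clipped at 0. A 2D
#' field is applied plane-wise to 3D volumes (dim (z, y, x)).
#'
#' @param volume 2D matrix or 3D array (z, y, x).
#' @param flatfield a \linkS4class{FlatField}.
#' @return corrected image of the same shape.
#' @export
correctIllumination <- function(volume, flatfield) {
  stopifnot(is(flatfield, "FlatField"))
  if (any(flatfield@flatfield <= 0))
    stop("flatfield must be strictly positive", call. = FALSE)
  ff <- flatfield@flatfield
  df <- flatfield@darkfield
  if (is.matrix(volume)) {
    if (!identical(dim(volume), dim(ff)))
      stop("flatfield shape does not match the image", call. = FALSE)
    return(pmax((volume - df) / ff, 0))
  }
  .check_volume(volume)
  d <- dim(volume)
  if (!identical(d[2:3], dim(ff)))
    stop("flatfield shape does not match the volume's (y, x) planes",
         call. = FALSE)
  out <- (volume - rep(df, each = d[1])) / rep(ff, each = d[1])
  pmax(out, 0)
}

#' True 3D median filter
#'
#' Replaces every voxel by the median of its kernel^3 neighbourhood
#' (default 3 x 3 x 3), with reflected borders. Used to suppress shot
#' noise before spot detection.
#'
#' @param volume 3D array (z, y, x).
#' @param kernel odd integer edge length, >= 1.
#' @return filtered volume, same shape.
#' @export
medianFilter3D <- function(volume, kernel = 3L) {
  .check_volume(volume)
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be an odd integer >= 1", call. = FALSE)
  if (kernel == 1L) return(volume)
  out <- cpp_median3d(volume, dim(volume), kernel)
  array(out, dim(volume))
}

#' Integer-voxel inter-round registration
#'
#' Finds the integer translation of \code{moving} relative to
#' \code{reference} by exhaustive search over shifts within
#' \code{maxShift}, maximising the Pearson correlation on the overlap.
#' The returned shift is the displacement of the moving volume's content:
#' applying the negated shift (\code{\link{applyShift}} with
#' \code{-shift}) aligns it to the reference.
#'
#' @param reference,moving 3D arrays of identical shape; use a stable
#'   channel (membrane or DAPI) of each round.
#' @param maxShift maximal |shift| per axis, scalar or length 3 (z, y, x);
#'   must be below half of each dimension.
#' @param scoreFloor correlations below this mark the result as low
#'   confidence (\code{lowConfidence = TRUE} plus a warning).
#' @return list with \code{shift} (integer (dz, dy, dx)), \code{score}
#'   (correlation in [-1, 1]) and \code{lowConfidence}.
#' @export
registerRounds <- function(reference, moving, maxShift = 10L,
                           scoreFloor = 0.3) {
  .check_volume(reference, "reference")
  .check_volume(moving, "moving")
  if (!identical(dim(reference), dim(moving)))
    stop("reference and moving must have identical shapes", call. = FALSE)
  ms <- as.integer(rep(maxShift, length.out = 3))
  if (any(ms < 0L))
    stop("maxShift must be non-negative", call. = FALSE)
  if (any(ms >= dim(reference) / 2))
    stop("maxShift must be below half of every dimension", call. = FALSE)
  res <- cpp_register_ncc(as.numeric(reference), as.numeric(moving),
                          dim(reference), ms)
  shift <- as.integer(res$shift)
  names(shift) <- c("dz", "dy", "dx")
  low <- res$score < scoreFloor
  if (low)
    warning(sprintf("registration score %.3f below floor %.2f; %s",
                    res$score, scoreFloor,
                    "alignment is low confidence"))
  list(shift = shift, score = res$score, lowConfidence = low)
}

#' Translate a volume by an integer shift
#'
#' Moves the content by \code{shift} voxels (z, y, x) with constant fill;
#' the translation is lossless where source and destination overlap.
#'
#' @param volume 3D array.
#' @param shift integer(3) displacement (dz, dy, dx).
#' @param fill value for vacated voxels.
#' @return translated volume, same shape.
#' @export
applyShift <- function(volume, shift, fill = 0) {
  .check_volume(volume)
  .translate(volume, as.integer(round(shift)), fill)
}

#' Preprocess one round stack
#'
#' The documented stage order: flat-field correction per channel, 3D
#' median filtering of the readout channels, then registration of the
#' round's membrane channel to the reference round's and application of
#' the negated shift to every channel.
#'
#' @param stack 4D array (z, y, x, channel).
#' @param flatfields list of \linkS4class{FlatField}, one per channel.
#' @param reference the reference round's registration channel (3D), or
#'   NULL to skip registration.
#' @param registrationChannel channel index used for alignment.
#' @param kernel median kernel (odd; 1 disables).
#' @param maxShift registration search radius.
#' @return list: \code{stack} (preprocessed, registered), \code{shift},
#'   \code{score}.
#' @export
preprocessStack <- function(stack, flatfields = NULL, reference = NULL,
                            registrationChannel = dim(stack)[4] - 1L,
                            kernel = 3L, maxShift = c(2L, 8L, 8L)) {
  stopifnot(length(dim(stack)) == 4L)
  nch <- dim(stack)[4]
  out <- stack
  for (ch in seq_len(nch)) {
    v <- out[, , , ch]
    if (!is.null(flatfields))
      v <- correctIllumination(v, flatfields[[ch]])
    if (kernel > 1L)
      v <- medianFilter3D(v, kernel)
    out[, , , ch] <- v
  }
  shift <- c(dz = 0L, dy = 0L, dx = 0L)
  score <- NA_real_
  if (!is.null(reference)) {
    reg <- registerRounds(reference, out[, , , registrationChannel],
                          maxShift = maxShift)
    shift <- reg$shift
    score <- reg$score
    if (any(shift != 0L))
      for (ch in seq_len(nch))
        out[, , , ch] <- .translate(out[, , , ch], -shift)
  }
  list(stack = out, shift = shift, score = score)
}
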