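`%||%` <- function(a, b) if (is.null(a)) b else a

# 1-D Gaussian kernel, odd length covering +-ext sigma, normalised to sum 1.
.gauss_kernel <- function(sigma, ext = 3) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(ext * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Separable 3D Gaussian smoothing; sigma is per-axis (z, y, x) in voxels.
.gauss3d <- function(vol, sigma) {
  d <- dim(vol)
  out <- vol
  for (ax in 1:3) {
    if (sigma[ax] > 0)
      out <- cpp_conv_axis(out, d, .gauss_kernel(sigma[ax]), ax - 1L)
  }
  out
}

# Negated Laplacian of the Gaussian-smoothed volume: positive blob response.
.neg_log_response <- function(vol, sigma) {
  d <- dim(vol)
  sm <- .gauss3d(vol, sigma)
  lap <- cpp_conv_axis(sm, d, c(1, -2, 1), 0L) +
         cpp_conv_axis(sm, d, c(1, -2, 1), 1L) +
         cpp_conv_axis(sm, d, c(1, -2, 1), 2L)
  -lap
}

# linear index -> 1-based (z, y, x) for dim d
.ind2zyx <- function(i, d) {
  i0 <- i - 1L
  cbind(z = (i0 %% d[1]) + 1L,
        y = ((i0 %/% d[1]) %% d[2]) + 1L,
        x = (i0 %/% (d[1] * d[2])) + 1L)
}

.zyx2ind <- function(z, y, x, d) {
  (z - 1L) + d[1] * ((y - 1L) + d[2] * (x - 1L)) + 1L
}

.check_volume <- function(vol, name = "volume") {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop(name, " must be a 3D array (z, y, x)", call. = FALSE)
  invisible(vol)
}

# Empty spot data.frame with the canonical column set.
.empty_spots <- function() {
  data.frame(spot_id = integer(), fov = integer(), round = integer(),
             channel = integer(), z = numeric(), y = numeric(),
             x = numeric(), intensity = numeric(),
             stringsAsFactors = FALSE)
}

#' Construct a SpotTable
#'
#' Wraps a data.frame (or DataFrame) of spot records into a validated
#' \linkS4class{SpotTable}. Missing optional columns are left absent;
#' required columns are checked by the class validity.
#'
#' @param df data.frame with at least the required spot columns
#'   (\code{spot_id}, \code{fov}, \code{round}, \code{channel}, \code{z},
#'   \code{y}, \code{x}, \code{intensity}).
#' @return a \linkS4class{SpotTable}.
#' @export
SpotTable <- function(df = .empty_spots()) {
  new("SpotTable", S4Vectors::DataFrame(df, check.names = FALSE))
}

# coerce SpotTable / DataFrame / data.frame to plain data.frame
.spot_df <- function(x) as.data.frame(x, optional = TRUE)
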