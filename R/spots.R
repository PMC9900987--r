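#' Construct a codebook
#'
#' @param genes ordered gene names; gene i is assigned round
#'   \code{ceiling(i / channelsPerRound)}, channel
#'   \code{(i - 1) \%\% channelsPerRound + 1} by
#'   \code{defaultCodebook}, or give explicit \code{rounds}/
#'   \code{channels}.
#' @param rounds,channels integer vectors parallel to \code{genes}.
#' @param nRounds,channelsPerRound layout capacity.
#' @return a validated \linkS4class{Codebook}.
#' @export
Codebook <- function(genes, rounds, channels,
                     nRounds = max(rounds),
                     channelsPerRound = max(channels)) {
  new("Codebook",
      entries = data.frame(round = as.integer(rounds),
                           channel = as.integer(channels),
                           gene = as.character(genes),
                           stringsAsFactors = FALSE),
      nRounds = as.integer(nRounds),
      channelsPerRound = as.integer(channelsPerRound))
}

#' @rdname Codebook
#' @export
defaultCodebook <- function(genes = defaultGenePanel(),
                            nRounds = ceiling(length(genes) / channelsPerRound),
                            channelsPerRound = 5L) {
  i <- seq_along(genes)
  Codebook(genes,
           rounds = (i - 1L) %/% channelsPerRound + 1L,
           channels = (i - 1L) %% channelsPerRound + 1L,
           nRounds = nRounds, channelsPerRound = channelsPerRound)
}

#' Detect candidate spots in one volume
#'
#' Laplacian-of-Gaussian blob detection: the volume is smoothed with an
#' anisotropic Gaussian at the spot scale, the negated Laplacian response
#' is computed, and local maxima above \code{minPeak} separated by at
#' least \code{minDistance} voxels (Chebyshev) are reported. The recorded
#' \code{intensity} is the input volume's value at the peak voxel.
#'
#' @param volume preprocessed 3D array (z, y, x).
#' @param sigma spot scale in um (isotropic in um).
#' @param voxelSize numeric(3) um per voxel.
#' @param minDistance minimal peak separation in voxels.
#' @param minPeak response threshold; NULL (default) sets it to
#'   \code{median + 8 * mad} of the response (with a small relative floor
#'   so featureless volumes yield no detections).
#' @param fov,round,channel metadata stamped on the records.
#' @return a \linkS4class{SpotTable} of candidates (no class, no gene).
#' @export
detectSpots <- function(volume, sigma = 0.25,
                        voxelSize = c(0.5, 0.21, 0.21),
                        minDistance = 1L, minPeak = NULL,
                        fov = 1L, round = 1L, channel = 1L) {
  .check_volume(volume)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  d <- dim(volume)
  resp <- .neg_log_response(volume, sigma / voxelSize)
  if (is.null(minPeak)) {
    minPeak <- stats::median(resp) + 8 * stats::mad(resp)
    minPeak <- max(minPeak, 1e-6 * max(resp), 1e-12)
  }
  r <- as.integer(max(1L, minDistance))
  idx <- cpp_local_max(resp, d, r, r, r, minPeak)
  if (!length(idx)) return(SpotTable())
  zyx <- .ind2zyx(idx, d)
  SpotTable(data.frame(
    spot_id = seq_along(idx),
    fov = as.integer(fov), round = as.integer(round),
    channel = as.integer(channel),
    z = zyx[, 1], y = zyx[, 2], x = zyx[, 3],
    intensity = volume[idx],
    response = resp[idx]))
}

# Exact 1-D k-means by dynamic programming over contiguous partitions of
# the sorted values; returns cluster index per input value (1 = lowest
# mean). The 1-D k-means optimum is always a contiguous partition, so the
# DP solves the problem globally and deterministically.
.kmeans1d <- function(x, k) {
  n <- length(x)
  o <- order(x)
  s <- x[o]
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  ssq <- function(i, j) {           # within-SS of s[i..j]
    su <- cs[j] - if (i > 1) cs[i - 1] else 0
    sq <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    sq - su^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) D[1, j] <- ssq(1, j)
  if (k > 1) for (q in 2:k) {
    for (j in q:n) {
      best <- Inf; bi <- q
      for (i in q:j) {
        v <- D[q - 1, i - 1] + ssq(i, j)
        if (v < best) { best <- v; bi <- i }
      }
      D[q, j] <- best; B[q, j] <- bi
    }
  }
  cl_sorted <- integer(n)
  j <- n
  for (q in k:1) {
    i <- if (q == 1) 1L else B[q, j]
    cl_sorted[i:j] <- q
    j <- i - 1L
    if (j < 1L) break
  }
  cl <- integer(n)
  cl[o] <- cl_sorted
  cl
}

#' K-means intensity gate: signal vs unspecific spots
#'
#' Separates true signal from unspecifically bound probe (which appears as
#' low-intensity dots) by k-means clustering of spot intensities,
#' independently within each (fov, round, channel) group since exposure
#' and laser power differ per fluorophore. The clustering is an exact 1-D
#' k-means (dynamic programming over contiguous partitions of the sorted
#' feature, globally optimal and deterministic); the cluster with the
#' highest mean intensity is labelled \code{"signal"}, all others
#' \code{"unspecific"}. Spots are labelled, never removed.
#'
#' Groups with fewer than k spots, or with zero intensity variance, cannot
#' be clustered: all their spots are labelled signal, with a warning.
#'
#' @param spots a \linkS4class{SpotTable} of candidates.
#' @param k number of intensity clusters (default 2).
#' @param logIntensity cluster log10(intensity) rather than raw intensity
#'   (default TRUE; intensities are floored at a tiny positive value).
#' @param by grouping columns (default fov, round, channel).
#' @return the table with a \code{class} column filled in.
#' @export
kmeansSignalGate <- function(spots, k = 2L, logIntensity = TRUE,
                             by = c("fov", "round", "channel")) {
  df <- .spot_df(spots)
  if (!nrow(df)) {
    df$class <- character(0)
    return(SpotTable(df))
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  feat <- if (logIntensity) log10(pmax(df$intensity, 1e-12)) else
    df$intensity
  df$class <- NA_character_
  grp <- interaction(df[, intersect(by, names(df)), drop = FALSE],
                     drop = TRUE)
  fellback <- FALSE
  for (g in levels(grp)) {
    ii <- which(grp == g)
    x <- feat[ii]
    if (length(ii) < k || stats::var(x) == 0) {
      df$class[ii] <- "signal"
      fellback <- TRUE
      next
    }
    cl <- .kmeans1d(x, k)
    mu <- tapply(x, cl, mean)
    hi <- as.integer(names(mu)[which.max(mu)])  # ties: first max = signal
    df$class[ii] <- ifelse(cl == hi, "signal", "unspecific")
  }
  if (fellback)
    warning("group(s) with < k spots or zero variance: all labelled signal")
  SpotTable(df)
}

#' Decode gene identity from the codebook
#'
#' Fills the \code{gene} column by (round, channel) lookup. Spots in
#' designated reference channels (membrane, DAPI) are dropped and their
#' count reported via a message.
#'
#' @param spots a \linkS4class{SpotTable}.
#' @param codebook a \linkS4class{Codebook}.
#' @param referenceChannels channel indices to drop (default none).
#' @return the table with \code{gene} populated.
#' @export
decodeGene <- function(spots, codebook, referenceChannels = integer()) {
  stopifnot(is(codebook, "Codebook"))
  df <- .spot_df(spots)
  if (length(referenceChannels)) {
    drop <- df$channel %in% referenceChannels
    if (any(drop))
      message(sum(drop), " reference-channel spot(s) dropped")
    df <- df[!drop, , drop = FALSE]
  }
  if (!nrow(df)) {
    df$gene <- character(0)
    return(SpotTable(df))
  }
  e <- codebook@entries
  key <- paste(df$round, df$channel)
  m <- match(key, paste(e$round, e$channel))
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("no codebook entry for (round, channel): ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  df$gene <- e$gene[m]
  SpotTable(df)
}
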