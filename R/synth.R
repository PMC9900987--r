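#' Default 30-gene ectodermal panel
#'
#' An ordered panel of thirty genes typical of early ectodermal patterning
#' work: the pluripotency trio (PouV/Oct4, Nanog, Klf4), pan-ectodermal
#' markers (Tfap2a, Sox2), neural-crest genes (Foxd3, cMyc, Pax7, Snai2,
#' Sox10, Sox9), neural genes (Nestin, MycN, Msi1), and border/placodal/
#' epidermal markers filling the panel to 30. Read out five genes per
#' round over six rounds by the default codebook.
#'
#' @return character vector of 30 gene names.
#' @export
defaultGenePanel <- function() {
  c("PouV", "Nanog", "Klf4", "Tfap2a", "Sox2",
    "Foxd3", "cMyc", "Pax7", "Snai2", "Sox10",
    "Sox9", "Nestin", "MycN", "Msi1", "Zic1",
    "Pax3", "Msx1", "Six1", "Eya2", "Dlx5",
    "Dlx6", "Gata2", "Gata3", "Otx2", "Gbx2",
    "Sox3", "Sox21", "Hes5", "Krt19", "Epcam")
}

#' Construct a subpopulation expression program
#'
#' @param name program name.
#' @param means named numeric vector of per-gene NB means; must cover the
#'   panel it will be used with.
#' @param domain fractional medio-lateral band of the section footprint
#'   (increasing pair within [0, 1]) where member cells are placed.
#' @param dispersion NB size parameter theta (variance = mu + mu^2/theta).
#' @param color display colour.
#' @return a \linkS4class{SubpopProgram}.
#' @export
SubpopProgram <- function(name, means, domain = c(0, 1),
                          dispersion = 8, color = "grey") {
  new("SubpopProgram", name = name, color = color,
      domain = as.numeric(domain), means = means,
      dispersion = as.numeric(dispersion))
}

#' Default four-program section layout
#'
#' Four transcriptional programs emulating an early ectoderm cross
#' section: a spatially unrestricted "stem" program co-expressing the
#' pluripotency trio plus Tfap2a and Sox2, and three committed programs
#' (neural, neural crest, epidermal) occupying medial-to-lateral bands.
#' Expression levels use three tiers: high (mu = 12), intermediate
#' (mu = 6) and basal (mu = 1), with NB size 8 throughout.
#'
#' @param panel the gene panel the programs must cover.
#' @return list of four \linkS4class{SubpopProgram} objects.
#' @export
defaultPrograms <- function(panel = defaultGenePanel()) {
  base_means <- function(high = character(), mid = character(),
                         hi = 12, md = 6, lo = 1) {
    m <- stats::setNames(rep(lo, length(panel)), panel)
    m[intersect(high, panel)] <- hi
    m[intersect(mid, panel)] <- md
    m
  }
  list(
    SubpopProgram("stem",
      base_means(high = c("PouV", "Nanog", "Klf4", "Tfap2a", "Sox2")),
      domain = c(0, 1), color = "#E41A1C"),
    SubpopProgram("neural",
      base_means(high = c("Nestin", "MycN", "Msi1"),
                 mid = c("Sox2", "Sox3", "Sox21", "Hes5", "Otx2")),
      domain = c(0, 1 / 3), color = "#377EB8"),
    SubpopProgram("neural_crest",
      base_means(high = c("Foxd3", "cMyc", "Pax7", "Snai2", "Sox10", "Sox9"),
                 mid = c("Tfap2a", "Zic1", "Pax3", "Msx1")),
      domain = c(1 / 3, 2 / 3), color = "#4DAF4A"),
    SubpopProgram("epidermal",
      base_means(high = c("Gata2", "Gata3", "Dlx5", "Dlx6", "Krt19", "Epcam"),
                 mid = c("Tfap2a", "Six1", "Eya2")),
      domain = c(2 / 3, 1), color = "#FF7F00"))
}

#' Simulation configuration constructor
#'
#' Defaults describe a desk-scale serial smFISH acquisition: 3 fields of
#' view per section, z-planes every 0.5 um, 5 readout channels per round
#' plus membrane and DAPI reference channels, 6 rounds covering a 30-gene
#' panel, diffraction-limited spots (sigma 0.25 um) of mean amplitude 1000
#' a.u. over unspecific background spots of mean 200 a.u., smooth
#' quadratic multiplicative shading of up to +-30 percent, integer-voxel
#' inter-round drift, and camera noise.
#'
#' @param volumeShape integer(3), voxels per FOV in (z, y, x).
#' @param voxelSize numeric(3), um per voxel (z, y, x).
#' @param nRounds,channelsPerRound acquisition layout.
#' @param genePanel ordered gene names.
#' @param nFOVs fields of view tiled along x.
#' @param nCells total cells in the section.
#' @param programs list of \linkS4class{SubpopProgram}.
#' @param backgroundSpotRate unspecific spots per 1000 um^3 per channel.
#' @param spotSigma spot Gaussian sigma in um (isotropic in um).
#' @param signalIntensity,backgroundIntensity (mean, sd) spot amplitudes.
#' @param baseline camera offset, a.u.
#' @param illumAmplitude peak fractional shading of the quadratic field.
#' @param driftMax integer(3), maximal |round shift| per axis; round 1 is
#'   the reference and never shifted.
#' @param roundShifts explicit nRounds x 3 integer matrix, or NULL to draw
#'   shifts uniformly within driftMax.
#' @param noiseSD additive Gaussian camera noise sd.
#' @param minSpotSeparation if > 0, signal spots within one
#'   (fov, round, channel) are placed with at least this Chebyshev voxel
#'   distance between them (used by the noiseless validation preset; spots
#'   closer than the PSF are unresolvable by any detector).
#' @param stage developmental stage label attached to all cells.
#' @param seed RNG seed; all generator randomness derives from it.
#' @return a validated \linkS4class{SimConfig}.
#' @export
SimConfig <- function(volumeShape = c(16L, 100L, 100L),
                      voxelSize = c(0.5, 0.21, 0.21),
                      nRounds = 6L,
                      channelsPerRound = 5L,
                      genePanel = defaultGenePanel(),
                      nFOVs = 3L,
                      nCells = 36L,
                      programs = defaultPrograms(genePanel),
                      backgroundSpotRate = 2,
                      spotSigma = 0.25,
                      signalIntensity = c(1000, 100),
                      backgroundIntensity = c(200, 25),
                      baseline = 100,
                      illumAmplitude = 0.3,
                      driftMax = c(1L, 4L, 4L),
                      roundShifts = NULL,
                      noiseSD = 10,
                      minSpotSeparation = 0L,
                      stage = "HH8",
                      seed = 1L) {
  new("SimConfig",
      volumeShape = as.integer(volumeShape),
      voxelSize = as.numeric(voxelSize),
      nRounds = as.integer(nRounds),
      channelsPerRound = as.integer(channelsPerRound),
      genePanel = as.character(genePanel),
      nFOVs = as.integer(nFOVs),
      nCells = as.integer(nCells),
      programs = programs,
      backgroundSpotRate = as.numeric(backgroundSpotRate),
      spotSigma = as.numeric(spotSigma),
      signalIntensity = as.numeric(signalIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      baseline = as.numeric(baseline),
      illumAmplitude = as.numeric(illumAmplitude),
      driftMax = as.integer(driftMax),
      roundShifts = if (is.null(roundShifts)) NULL else {
        m <- as.matrix(roundShifts); storage.mode(m) <- "integer"; m
      },
      noiseSD = as.numeric(noiseSD),
      minSpotSeparation = as.integer(minSpotSeparation),
      stage = as.character(stage),
      seed = as.integer(seed))
}

#' Named simulation presets
#'
#' \code{"default"} is the standard noisy section (see
#' \code{\link{SimConfig}}); \code{"noiseless"} switches off camera noise,
#' background spots, shading and drift and enforces a 4-voxel minimum
#' spot separation, giving a scene in which every rendered local maximum
#' is one resolvable true spot; \code{"tiny"} is a single small FOV with a
#' 6-gene panel for fast smoke tests.
#'
#' @param name one of "default", "noiseless", "tiny".
#' @param seed RNG seed.
#' @param ... overrides passed on to \code{\link{SimConfig}}.
#' @return a \linkS4class{SimConfig}.
#' @export
simPreset <- function(name = c("default", "noiseless", "tiny"),
                      seed = 1L, ...) {
  name <- match.arg(name)
  over <- list(...)
  args <- switch(name,
    default = list(),
    noiseless = list(noiseSD = 0, backgroundSpotRate = 0,
                     illumAmplitude = 0, driftMax = c(0L, 0L, 0L),
                     minSpotSeparation = 4L, nCells = 18L),
    tiny = {
      panel <- defaultGenePanel()[1:6]
      list(volumeShape = c(10L, 48L, 48L), nFOVs = 1L, nCells = 8L,
           voxelSize = c(0.5, 0.42, 0.42),
           nRounds = 2L, channelsPerRound = 3L, genePanel = panel,
           programs = lapply(defaultPrograms(), function(p)
             SubpopProgram(p@name, p@means[panel], p@domain,
                           p@dispersion, p@color)))
    })
  args[names(over)] <- over
  args$seed <- seed
  do.call(SimConfig, args)
}

#' Smooth quadratic shading field
#'
#' Generates a random low-order polynomial multiplicative illumination
#' surface: 1 plus a mean-centred quadratic in (y, x) scaled so its peak
#' deviation equals \code{amplitude}, then renormalised to spatial mean 1.
#'
#' @param ny,nx field dimensions.
#' @param amplitude peak fractional deviation from flat (0 gives a field
#'   of ones); must be < 1 so the field stays positive.
#' @return ny x nx positive matrix with mean 1.
#' @export
simulateShadingField <- function(ny, nx, amplitude = 0.3) {
  if (amplitude >= 1) stop("amplitude must be < 1", call. = FALSE)
  if (amplitude <= 0) return(matrix(1, ny, nx))
  u <- seq(-1, 1, length.out = ny)
  v <- seq(-1, 1, length.out = nx)
  co <- stats::rnorm(5)
  q <- outer(u, v, function(a, b)
    co[1] * a + co[2] * b + co[3] * a * a + co[4] * b * b + co[5] * a * b)
  q <- q - mean(q)
  pk <- max(abs(q))
  f <- if (pk > 0) 1 + amplitude * q / pk else matrix(1, ny, nx)
  f / mean(f)
}

# Poisson-disc-ish centroid placement across the section footprint.
# Returns data.frame(cell_id, program, xs (section um), ys, zs, fov,
# z/y/x voxel coords within the FOV).
.place_cells <- function(config) {
  d <- config@volumeShape
  vs <- config@voxelSize
  nP <- length(config@programs)
  prog_idx <- rep(seq_len(nP), length.out = config@nCells)
  prog_idx <- sample(prog_idx)          # shuffle program order over cells
  width_frac <- 1 / config@nFOVs
  min_sep_um <- 2.5
  xs <- ys <- zs <- numeric(config@nCells)
  sect_w <- config@nFOVs * d[3] * vs[3]
  for (i in seq_len(config@nCells)) {
    dom <- config@programs[[prog_idx[i]]]@domain
    ok <- FALSE
    for (try in 1:200) {
      xf <- stats::runif(1, dom[1], dom[2])
      x <- xf * sect_w
      y <- stats::runif(1, 2 * vs[2], (d[2] - 2) * vs[2])
      z <- stats::runif(1, 1.5 * vs[1], (d[1] - 1.5) * vs[1])
      if (i == 1L ||
          min(sqrt((xs[seq_len(i - 1)] - x)^2 +
                   (ys[seq_len(i - 1)] - y)^2 +
                   (zs[seq_len(i - 1)] - z)^2)) > min_sep_um) {
        ok <- TRUE; break
      }
    }
    xs[i] <- x; ys[i] <- y; zs[i] <- z
    if (!ok) next  # accept last draw; density too high for the separation
  }
  xf_all <- xs / sect_w
  fov <- pmin(config@nFOVs, floor(xf_all / width_frac) + 1L)
  x_vox <- (xs - (fov - 1L) * d[3] * vs[3]) / vs[3] + 0.5
  x_vox <- pmin(pmax(x_vox, 1.5), d[3] - 0.5)
  data.frame(cell_id = seq_len(config@nCells),
             program = vapply(config@programs, function(p) p@name,
                              "")[prog_idx],
             program_idx = prog_idx,
             xs = xs, ys = ys, zs = zs, fov = as.integer(fov),
             z = zs / vs[1] + 0.5, y = ys / vs[2] + 0.5, x = x_vox)
}

# NB count matrix (genes x cells) for placed cells.
.draw_counts <- function(config, cells) {
  panel <- config@genePanel
  counts <- matrix(0L, length(panel), nrow(cells),
                   dimnames = list(panel, as.character(cells$cell_id)))
  for (j in seq_len(nrow(cells))) {
    p <- config@programs[[cells$program_idx[j]]]
    counts[, j] <- as.integer(stats::rnbinom(length(panel),
                                             mu = p@means[panel],
                                             size = p@dispersion))
  }
  counts
}

.counts_sce <- function(config, cells, counts) {
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      cell_id = cells$cell_id,
      fov = cells$fov,
      section = 1L,
      stage = config@stage,
      program = cells$program,
      centroid_z = cells$z, centroid_y = cells$y, centroid_x = cells$x,
      row.names = as.character(cells$cell_id)),
    metadata = list(genePanel = config@genePanel, stage = config@stage))
}

#' Simulate a count matrix directly (no image rendering)
#'
#' Draws per-cell negative-binomial transcript counts from the configured
#' subpopulation programs and places cell centroids inside each program's
#' spatial band of the section footprint. Deterministic for a fixed
#' config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SingleCellExperiment} with assay
#'   \code{"counts"}; colData carries the planted program of every cell
#'   (\code{program}), its FOV, stage and centroid (voxel units).
#' @export
simulateCounts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  cells <- .place_cells(config)
  counts <- .draw_counts(config, cells)
  .counts_sce(config, cells, counts)
}

# boundary mask (6-connectivity) of a label array: voxel whose neighbour
# along any axis carries a different label
.boundary_mask <- function(lab) {
  d <- dim(lab)
  b <- array(FALSE, d)
  b[-d[1], , ] <- b[-d[1], , ] | (lab[-d[1], , ] != lab[-1, , ])
  b[-1, , ]    <- b[-1, , ]    | (lab[-d[1], , ] != lab[-1, , ])
  b[, -d[2], ] <- b[, -d[2], ] | (lab[, -d[2], ] != lab[, -1, ])
  b[, -1, ]    <- b[, -1, ]    | (lab[, -d[2], ] != lab[, -1, ])
  b[, , -d[3]] <- b[, , -d[3]] | (lab[, , -d[3]] != lab[, , -1])
  b[, , -1]    <- b[, , -1]    | (lab[, , -d[3]] != lab[, , -1])
  b
}

# integer-voxel translation with constant fill:
# out[p + shift] = vol[p]  (content moves BY +shift)
.translate <- function(vol, shift, fill = 0) {
  d <- dim(vol)
  out <- array(fill, d)
  src <- dst <- list()
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    src[[ax]] <- if (s >= 0) 1:(d[ax] - s) else (1 - s):d[ax]
    dst[[ax]] <- if (s >= 0) (1 + s):d[ax] else 1:(d[ax] + s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Simulate a full multi-round section with ground truth
#'
#' Renders one synthetic section: cells are anisotropic Voronoi regions
#' around Poisson-disc-placed centroids filling each FOV; each readout
#' channel of each round carries 3D Gaussian spots for the gene assigned
#' by the codebook (amplitudes from the signal distribution) plus
#' uniformly placed low-intensity unspecific spots; every round also
#' carries a membrane channel (blurred ridge image of the cell
#' boundaries) and a DAPI channel (blurred nuclear blobs). Per-round
#' integer drift, per-channel multiplicative quadratic shading, a camera
#' baseline and Gaussian noise are applied in that order. Deterministic
#' for a fixed config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{stacks} (list over FOVs; each a list
#'   over rounds of 4D arrays (z, y, x, channel) with channels 1..
#'   channelsPerRound = readout, then membrane, then DAPI),
#'   \code{codebook} (the \linkS4class{Codebook} used) and \code{truth}
#'   (a \linkS4class{GroundTruth}).
#' @export
simulateSection <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  d <- config@volumeShape
  vs <- config@voxelSize
  cb <- defaultCodebook(config@genePanel, config@nRounds,
                        config@channelsPerRound)
  n_chan <- config@channelsPerRound + 2L
  sigma_vox <- config@spotSigma / vs

  # camera-fixed shading per channel
  fields <- lapply(seq_len(n_chan), function(ch)
    simulateShadingField(d[2], d[3], config@illumAmplitude))

  # per-round drift; round 1 is the reference
  shifts <- config@roundShifts
  if (is.null(shifts)) {
    shifts <- t(vapply(seq_len(config@nRounds), function(r) {
      if (r == 1L) c(0L, 0L, 0L) else
        vapply(1:3, function(ax)
          if (config@driftMax[ax] > 0L)
            sample(seq(-config@driftMax[ax], config@driftMax[ax]), 1L)
          else 0L, integer(1))
    }, integer(3)))
  }
  dimnames(shifts) <- list(NULL, c("dz", "dy", "dx"))

  cells <- .place_cells(config)
  counts <- .draw_counts(config, cells)

  # Voronoi label volume per FOV (global cell ids)
  label_vols <- vector("list", config@nFOVs)
  cell_voxels <- vector("list", nrow(cells))
  for (f in seq_len(config@nFOVs)) {
    idx <- which(cells$fov == f)
    lab <- array(0L, d)
    if (length(idx)) {
      cents <- cbind(cells$z[idx], cells$y[idx], cells$x[idx]) - 1  # 0-based
      lab <- cpp_voronoi_labels(d, cents, vs,
                                rep(TRUE, prod(d)))
      lab <- array(cells$cell_id[idx][lab], d)
      storage.mode(lab) <- "integer"
      vox <- split(seq_len(prod(d)), lab)
      for (id in names(vox))
        cell_voxels[[as.integer(id)]] <- vox[[id]]
    }
    label_vols[[f]] <- new("LabelVolume", labels = lab, voxelSize = vs)
  }

  # place true signal spots; in resolvable-spot mode (minSpotSeparation
  # > 0) placements keep a 2-voxel margin from the volume border, since
  # border-truncated spots are not reliably localizable by construction
  interior <- NULL
  if (config@minSpotSeparation > 0L) {
    zyx_all <- .ind2zyx(seq_len(prod(d)), d)
    interior <- which(zyx_all[, 1] >= 3L & zyx_all[, 1] <= d[1] - 2L &
                      zyx_all[, 2] >= 3L & zyx_all[, 2] <= d[2] - 2L &
                      zyx_all[, 3] >= 3L & zyx_all[, 3] <= d[3] - 2L)
  }
  spot_list <- list()
  ent <- cb@entries
  for (j in seq_len(nrow(cells))) {
    id <- cells$cell_id[j]
    vox <- cell_voxels[[id]]
    if (is.null(vox) || !length(vox)) next
    if (!is.null(interior)) {
      vin <- intersect(vox, interior)
      if (length(vin)) vox <- vin   # fall back for fully peripheral cells
    }
    for (gi in seq_along(config@genePanel)) {
      n <- counts[gi, j]
      if (n == 0L) next
      g <- config@genePanel[gi]
      rr <- ent$round[ent$gene == g]
      ch <- ent$channel[ent$gene == g]
      pick <- vox[sample.int(length(vox), n, replace = TRUE)]
      zyx <- .ind2zyx(pick, d)
      jit <- matrix(stats::runif(3 * n, -0.3, 0.3), n, 3)
      spot_list[[length(spot_list) + 1L]] <- data.frame(
        fov = cells$fov[j], round = rr, channel = ch, gene = g,
        z = zyx[, 1] + jit[, 1], y = zyx[, 2] + jit[, 2],
        x = zyx[, 3] + jit[, 3],
        amplitude = pmax(1, stats::rnorm(n, config@signalIntensity[1],
                                         config@signalIntensity[2])),
        class = "signal", cell_id = id)
    }
  }
  spots <- if (length(spot_list)) do.call(rbind, spot_list) else
    cbind(.empty_spots()[0, c("fov", "round", "channel")],
          data.frame(gene = character(), z = numeric(), y = numeric(),
                     x = numeric(), amplitude = numeric(),
                     class = character(), cell_id = integer()))

  # enforce minimum spot separation within each (fov, round, channel);
  # spots that cannot be placed at the required separation (cell too
  # crowded) are dropped and the corresponding true count decremented,
  # keeping the ground truth self-consistent with the rendered images
  if (config@minSpotSeparation > 0L && nrow(spots)) {
    sep <- config@minSpotSeparation
    drop <- rep(FALSE, nrow(spots))
    grp <- interaction(spots$fov, spots$round, spots$channel, drop = TRUE)
    for (g in levels(grp)) {
      ii <- which(grp == g)
      for (m in seq_along(ii)) {
        if (m == 1L) next
        i <- ii[m]
        prev <- ii[seq_len(m - 1L)]
        prev <- prev[!drop[prev]]
        if (!length(prev)) next
        vox <- cell_voxels[[spots$cell_id[i]]]
        if (!is.null(interior)) {
          vin <- intersect(vox, interior)
          if (length(vin)) vox <- vin
        }
        placed <- FALSE
        for (try in 1:500) {
          dmin <- min(pmax(abs(spots$z[prev] - spots$z[i]),
                           pmax(abs(spots$y[prev] - spots$y[i]),
                                abs(spots$x[prev] - spots$x[i]))))
          if (dmin >= sep) { placed <- TRUE; break }
          p <- vox[sample.int(length(vox), 1L)]
          zyx <- .ind2zyx(p, d)
          spots$z[i] <- zyx[1] + stats::runif(1, -0.3, 0.3)
          spots$y[i] <- zyx[2] + stats::runif(1, -0.3, 0.3)
          spots$x[i] <- zyx[3] + stats::runif(1, -0.3, 0.3)
        }
        if (!placed) drop[i] <- TRUE
      }
    }
    if (any(drop)) {
      dd <- spots[drop, , drop = FALSE]
      for (q in seq_len(nrow(dd))) {
        gi <- match(dd$gene[q], config@genePanel)
        cj <- match(dd$cell_id[q], cells$cell_id)
        counts[gi, cj] <- counts[gi, cj] - 1L
      }
      spots <- spots[!drop, , drop = FALSE]
    }
  }

  # unspecific background spots, uniform over each FOV volume
  fov_um3 <- prod(d * vs)
  bg_list <- list()
  for (f in seq_len(config@nFOVs)) {
    for (r in seq_len(config@nRounds)) {
      for (ch in seq_len(config@channelsPerRound)) {
        nbg <- stats::rpois(1, config@backgroundSpotRate * fov_um3 / 1000)
        if (nbg == 0L) next
        bg_list[[length(bg_list) + 1L]] <- data.frame(
          fov = f, round = r, channel = ch, gene = NA_character_,
          z = stats::runif(nbg, 1, d[1]), y = stats::runif(nbg, 1, d[2]),
          x = stats::runif(nbg, 1, d[3]),
          amplitude = pmax(1, stats::rnorm(nbg,
                                           config@backgroundIntensity[1],
                                           config@backgroundIntensity[2])),
          class = "unspecific", cell_id = 0L)
      }
    }
  }
  if (length(bg_list)) spots <- rbind(spots, do.call(rbind, bg_list))

  # drop spots whose drifted peak leaves the imaged volume: rendering
  # translates each round by its shift, so such spots are never imaged
  # and cannot be part of the observable ground truth; signal drops
  # decrement the true count of their (gene, cell)
  if (nrow(spots) && any(shifts != 0L)) {
    sh <- shifts[spots$round, , drop = FALSE]
    pz <- round(spots$z) + sh[, 1]
    py <- round(spots$y) + sh[, 2]
    px <- round(spots$x) + sh[, 3]
    obs <- pz >= 1 & pz <= d[1] & py >= 1 & py <= d[2] &
           px >= 1 & px <= d[3]
    if (any(!obs)) {
      dd <- spots[!obs & spots$class == "signal", , drop = FALSE]
      for (q in seq_len(nrow(dd))) {
        gi <- match(dd$gene[q], config@genePanel)
        cj <- match(dd$cell_id[q], cells$cell_id)
        counts[gi, cj] <- counts[gi, cj] - 1L
      }
      spots <- spots[obs, , drop = FALSE]
    }
  }
  if (nrow(spots)) {
    spots <- spots[order(spots$fov, spots$round, spots$channel,
                         spots$x, spots$y, spots$z), , drop = FALSE]
    spots <- cbind(spot_id = seq_len(nrow(spots)), spots)
    rownames(spots) <- NULL
    spots$intensity <- spots$amplitude
  } else {
    spots <- cbind(spot_id = integer(), spots, intensity = numeric())
  }

  # render
  stacks <- vector("list", config@nFOVs)
  for (f in seq_len(config@nFOVs)) {
    lab <- labelArray(label_vols[[f]])
    memb0 <- array(0, d)
    if (any(lab > 0L)) {
      memb0[.boundary_mask(lab)] <- 1
      memb0 <- .gauss3d(memb0, c(0.6, 0.8, 0.8)) *
        0.6 * config@signalIntensity[1] * 3
    }
    dapi0 <- array(0, d)
    idx <- which(cells$fov == f)
    for (j in idx)
      cpp_add_blob(dapi0, d, cells$z[j] - 1, cells$y[j] - 1, cells$x[j] - 1,
                   1.5 / vs[1], 1.5 / vs[2], 1.5 / vs[3],
                   0.8 * config@signalIntensity[1], 3)
    rounds <- vector("list", config@nRounds)
    for (r in seq_len(config@nRounds)) {
      arr <- array(0, c(d, n_chan))
      for (ch in seq_len(config@channelsPerRound)) {
        img <- array(0, d)
        ss <- spots[spots$fov == f & spots$round == r &
                    spots$channel == ch, , drop = FALSE]
        for (m in seq_len(nrow(ss)))
          cpp_add_blob(img, d, ss$z[m] - 1, ss$y[m] - 1, ss$x[m] - 1,
                       sigma_vox[1], sigma_vox[2], sigma_vox[3],
                       ss$amplitude[m], 3)
        arr[, , , ch] <- img
      }
      arr[, , , config@channelsPerRound + 1L] <- memb0
      arr[, , , config@channelsPerRound + 2L] <- dapi0
      for (ch in seq_len(n_chan)) {
        img <- .translate(arr[, , , ch], shifts[r, ])
        img <- img * rep(fields[[ch]], each = d[1])
        img <- img + config@baseline
        if (config@noiseSD > 0)
          img <- img + stats::rnorm(length(img), 0, config@noiseSD)
        arr[, , , ch] <- pmax(img, 0)
      }
      rounds[[r]] <- arr
    }
    stacks[[f]] <- rounds
  }

  sce <- .counts_sce(config, cells, counts)
  truth <- new("GroundTruth",
    labelVolumes = label_vols,
    trueSpots = SpotTable(spots[, c("spot_id", "fov", "round", "channel",
                                    "z", "y", "x", "intensity", "gene",
                                    "class", "cell_id")]),
    trueCounts = sce,
    cellSubpop = stats::setNames(cells$program, cells$cell_id),
    appliedShifts = shifts,
    appliedFlatfields = fields)
  list(stacks = stacks, codebook = cb, truth = truth, config = config)
}
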