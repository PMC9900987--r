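#' Assign spots to segmented cells
#'
#' Sets \code{cell_id} to the label value at each spot's (rounded) voxel;
#' 0 marks background. Spots falling outside the volume after rounding are
#' assigned 0 and counted in a warning. Spot coordinates must be in the
#' registered frame of the label volume; with multiple FOVs pass a list of
#' label volumes indexed by the table's \code{fov} column.
#'
#' @param spots a \linkS4class{SpotTable}.
#' @param labels a \linkS4class{LabelVolume} or a list of them (per FOV).
#' @return the table with \code{cell_id} filled in.
#' @export
assignSpotsToCells <- function(spots, labels) {
  if (is(labels, "LabelVolume")) labels <- list(labels)
  df <- .spot_df(spots)
  df$cell_id <- rep(0L, nrow(df))
  n_oob <- 0L
  for (f in unique(df$fov)) {
    lv <- labels[[f]]
    if (is.null(lv)) stop("no label volume for fov ", f, call. = FALSE)
    lab <- labelArray(lv)
    d <- dim(lab)
    ii <- which(df$fov == f)
    z <- as.integer(round(df$z[ii]))
    y <- as.integer(round(df$y[ii]))
    x <- as.integer(round(df$x[ii]))
    inb <- z >= 1L & z <= d[1] & y >= 1L & y <= d[2] & x >= 1L & x <= d[3]
    n_oob <- n_oob + sum(!inb)
    idx <- .zyx2ind(z[inb], y[inb], x[inb], d)
    df$cell_id[ii[inb]] <- lab[idx]
  }
  if (n_oob > 0L)
    warning(n_oob, " spot(s) outside volume bounds left unassigned")
  SpotTable(df)
}

#' Build the gene x cell count matrix
#'
#' Counts signal spots per (gene, cell) into a
#' \linkS4class{SingleCellExperiment}. Rows are the full codebook panel in
#' codebook order (all-zero rows kept); columns are QC-passing cells.
#' Background-assigned spots (cell_id 0) and spots gated unspecific are
#' never counted. Global cell ids are \code{fov * offset + local id},
#' flattened deterministically, exposed in colData together with FOV,
#' stage, centroid (voxel units) and cell volume (um^3).
#'
#' @param spots decoded, gated, cell-assigned \linkS4class{SpotTable}.
#' @param codebook the \linkS4class{Codebook}; spots with genes outside it
#'   raise a consistency error.
#' @param labels \linkS4class{LabelVolume} or per-FOV list.
#' @param minSpotsPerCell drop cells with fewer total signal spots
#'   (default 0 = off).
#' @param minCellVolume drop cells smaller than this many um^3 (default 0).
#' @param stage stage label stored per cell.
#' @param fovTrim fraction (0..0.5) of each FOV's width treated as overlap
#'   with the previous FOV: cells of FOV f > 1 whose centroid x lies in
#'   the leading trim band are dropped to avoid double counting.
#' @return a \linkS4class{SingleCellExperiment} with assay \code{"counts"}.
#' @export
buildCountMatrix <- function(spots, codebook, labels,
                             minSpotsPerCell = 0L, minCellVolume = 0,
                             stage = "unknown", fovTrim = 0) {
  stopifnot(is(codebook, "Codebook"))
  if (is(labels, "LabelVolume")) labels <- list(labels)
  df <- .spot_df(spots)
  panel <- genePanel(codebook)
  if (nrow(df)) {
    if (!("gene" %in% names(df)))
      stop("spots must be decoded before counting", call. = FALSE)
    unknown <- setdiff(unique(df$gene), c(panel, NA))
    if (length(unknown))
      stop("spot gene(s) absent from codebook: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }

  # cell roster from the label volumes (cells exist even with zero spots)
  rosters <- lapply(seq_along(labels), function(f) {
    lv <- labels[[f]]
    ids <- cellIds(lv)
    if (!length(ids))
      return(data.frame(fov = integer(), local_id = integer(),
                        z = numeric(), y = numeric(), x = numeric(),
                        volume = numeric()))
    cent <- cellCentroids(lv)
    vol <- cellVolumes(lv)
    data.frame(fov = f, local_id = ids,
               z = cent[as.character(ids), "z"],
               y = cent[as.character(ids), "y"],
               x = cent[as.character(ids), "x"],
               volume = vol[as.character(ids)])
  })
  roster <- do.call(rbind, rosters)
  if (fovTrim > 0 && nrow(roster)) {
    keep <- rep(TRUE, nrow(roster))
    for (f in seq_along(labels)) {
      if (f == 1L) next
      nx <- dim(labelArray(labels[[f]]))[3]
      keep[roster$fov == f & roster$x <= fovTrim * nx] <- FALSE
    }
    roster <- roster[keep, , drop = FALSE]
  }
  if (nrow(roster)) {
    roster <- roster[order(roster$fov, roster$local_id), , drop = FALSE]
    roster$cell <- paste(roster$fov, roster$local_id, sep = "_")
  } else roster$cell <- character(0)

  counts <- matrix(0L, length(panel), nrow(roster),
                   dimnames = list(panel, roster$cell))
  if (nrow(df)) {
    use <- df$cell_id > 0L
    if ("class" %in% names(df)) use <- use & df$class %in% "signal"
    dd <- df[use, , drop = FALSE]
    if (nrow(dd)) {
      cell_key <- paste(dd$fov, dd$cell_id, sep = "_")
      ok <- cell_key %in% roster$cell
      dd <- dd[ok, , drop = FALSE]
      cell_key <- cell_key[ok]
      if (nrow(dd)) {
        tab <- table(factor(dd$gene, levels = panel),
                     factor(cell_key, levels = roster$cell))
        counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                         dimnames = unname(dimnames(tab)))
      }
    }
  }

  # QC filters: volume, then spots per cell
  keep <- rep(TRUE, ncol(counts))
  if (minCellVolume > 0) keep <- keep & roster$volume >= minCellVolume
  if (minSpotsPerCell > 0) keep <- keep & colSums(counts) >= minSpotsPerCell
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(n_drop, " cell(s) dropped by QC filters")
  counts <- counts[, keep, drop = FALSE]
  roster <- roster[keep, , drop = FALSE]

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      cell_id = roster$cell, fov = roster$fov,
      local_id = roster$local_id,
      section = rep(1L, nrow(roster)),
      stage = rep(stage, nrow(roster)),
      centroid_z = roster$z, centroid_y = roster$y,
      centroid_x = roster$x, volume = roster$volume,
      row.names = roster$cell),
    metadata = list(genePanel = panel))
}
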