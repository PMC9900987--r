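#' Back-map cell groups onto the section image
#'
#' Pseudo-colours each cell of a label volume with its group colour
#' (subpopulation or gate membership) and projects to 2D, reproducing the
#' spatial location of transcriptional groups in the original tissue
#' section. Cells without a colour are painted a neutral grey; background
#' keeps the background colour. An optional grayscale underlay (for
#' example the membrane channel) is alpha-blended beneath the colouring.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param coloring named character vector, cell id -> colour (any R
#'   colour); may cover any subset of cells (empty is allowed).
#' @param projection "max" for the full-footprint z-projection, or an
#'   integer z-plane index.
#' @param background,unassigned colours for label 0 and uncoloured cells.
#' @param underlay optional 3D array matching the labels, shown in
#'   grayscale beneath the cell colours.
#' @param underlayOpacity blending weight of the underlay in [0, 1].
#' @return an (ny, nx, 3) RGB array in [0, 1] with attribute
#'   \code{"legend"} (colour -> group, as supplied via names).
#' @export
backmap <- function(labels, coloring = character(),
                    projection = "max", background = "black",
                    unassigned = "grey40", underlay = NULL,
                    underlayOpacity = 0.5) {
  stopifnot(is(labels, "LabelVolume"))
  lab <- labelArray(labels)
  d <- dim(lab)
  if (identical(projection, "max")) {
    # per-pixel: the largest coloured label in the column, else the
    # largest label, else 0 (deterministic footprint projection)
    flat <- .project_labels(lab, names(coloring))
  } else {
    kz <- as.integer(projection)
    if (is.na(kz) || kz < 1L || kz > d[1])
      stop("plane index out of range", call. = FALSE)
    flat <- matrix(lab[kz, , ], d[2], d[3])
  }
  ids <- sort(unique(as.vector(flat)))
  ids <- ids[ids > 0L]
  cols <- stats::setNames(rep(unassigned, length(ids)), as.character(ids))
  known <- intersect(names(coloring), names(cols))
  cols[known] <- coloring[known]
  lut <- c(background, cols)                       # index 1 = background
  rgb_lut <- t(grDevices::col2rgb(lut) / 255)
  pix <- match(as.vector(flat), c(0L, ids))
  img <- array(0, c(d[2], d[3], 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb_lut[pix, ch], d[2], d[3])
  if (!is.null(underlay)) {
    .check_volume(underlay, "underlay")
    if (!identical(dim(underlay), d))
      stop("underlay shape must match the label volume", call. = FALSE)
    g <- if (identical(projection, "max"))
      apply(underlay, c(2, 3), max) else matrix(underlay[kz, , ], d[2], d[3])
    rg <- range(g)
    g <- if (diff(rg) > 0) (g - rg[1]) / diff(rg) else g * 0
    a <- underlayOpacity
    for (ch in 1:3) img[, , ch] <- (1 - a) * img[, , ch] + a * g
  }
  attr(img, "legend") <- coloring
  img
}

# z-projection of a label volume preferring coloured labels so a coloured
# cell is never hidden by an uncoloured one lying above it
.project_labels <- function(lab, colored_ids) {
  d <- dim(lab)
  colored <- array(lab %in% as.integer(colored_ids), d)
  top_col <- apply(ifelse(colored, lab, 0L), c(2, 3), max)
  top_any <- apply(lab, c(2, 3), max)
  out <- ifelse(top_col > 0L, top_col, top_any)
  matrix(as.integer(out), d[2], d[3])
}

#' Write a back-mapped image to PNG with a JSON legend
#'
#' @param img RGB array from \code{\link{backmap}}.
#' @param path output PNG path; the legend (cell/group -> colour) is
#'   written next to it as \code{<path>.legend.json}.
#' @return invisibly, the PNG path.
#' @export
writeBackmap <- function(img, path) {
  png::writePNG(img, path)
  legend <- attr(img, "legend")
  jsonlite::write_json(as.list(legend %||% stats::setNames(list(), character())),
                       paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Colour cells by cluster or gate
#'
#' Convenience mappings from analysis results to the \code{coloring}
#' argument of \code{\link{backmap}}: every clustered cell gets its
#' cluster's colour, or every gated cell one highlight colour. Cell ids of
#' the count matrix are "fov_localid"; \code{fov} selects one FOV's local
#' ids for painting its label volume.
#'
#' @param x a \linkS4class{ClusterAssignment} or \linkS4class{GateResult}.
#' @param fov FOV whose cells to extract.
#' @param highlight colour for gated cells.
#' @return named character vector, local cell id -> colour.
#' @export
cellColoring <- function(x, fov = 1L, highlight = "#FFD700") {
  if (is(x, "ClusterAssignment")) {
    ids <- names(x@cluster)
    col <- stats::setNames(x@colors[as.character(x@cluster)], ids)
    sel <- ids[startsWith(ids, paste0(fov, "_"))]
    stats::setNames(col[sel], sub("^[0-9]+_", "", sel))
  } else if (is(x, "GateResult")) {
    sel <- x@cellIds[startsWith(x@cellIds, paste0(fov, "_"))]
    stats::setNames(rep(highlight, length(sel)), sub("^[0-9]+_", "", sel))
  } else stop("x must be a ClusterAssignment or GateResult", call. = FALSE)
}
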