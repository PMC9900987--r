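#' Volume and table input/output
#'
#' Readers and writers for the pipeline's artifacts: multi-page TIFF
#' volumes (float32, or integer for label masks with automatic promotion
#' from 16 to 32 bit when labels exceed 65535), spot tables and shift
#' tables as CSV with schema validation, count matrices as MatrixMarket
#' MTX with gene and cell-metadata sidecars, and codebooks as YAML or
#' JSON. All round-trips are lossless for the value ranges involved.
#'
#' @name muxfish-io
NULL

#' @rdname muxfish-io
#' @param volume 3D array (z, y, x); pages are z-planes.
#' @param path file path.
#' @param integer write (and read) integer samples rather than float32.
#' @return \code{readVolumeTIFF}: the volume; writers return the path
#'   invisibly.
#' @export
writeVolumeTIFF <- function(volume, path, integer = FALSE) {
  .check_volume(volume)
  d <- dim(volume)
  planes <- lapply(seq_len(d[1]), function(z) matrix(volume[z, , ], d[2], d[3]))
  if (integer) {
    mx <- max(volume, 0)
    bits <- if (mx > 65535) 32L else 16L
    denom <- 2^bits - 1
    tiff::writeTIFF(lapply(planes, function(p) p / denom), path,
                    bits.per.sample = bits)
  } else {
    tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' @rdname muxfish-io
#' @export
readVolumeTIFF <- function(path, integer = FALSE) {
  pl <- tiff::readTIFF(path, all = TRUE, as.is = integer)
  if (!is.list(pl)) pl <- list(pl)
  d <- c(length(pl), dim(pl[[1]]))
  out <- array(if (integer) 0L else 0, d)
  for (z in seq_len(d[1])) out[z, , ] <- pl[[z]]
  if (integer) storage.mode(out) <- "integer"
  out
}

#' @rdname muxfish-io
#' @param labels a \linkS4class{LabelVolume}.
#' @export
writeLabels <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  writeVolumeTIFF(labelArray(labels), path, integer = TRUE)
}

#' @rdname muxfish-io
#' @param spots a \linkS4class{SpotTable} (or data.frame with the spot
#'   schema).
#' @export
writeSpotTable <- function(spots, path) {
  utils::write.csv(.spot_df(spots), path, row.names = FALSE)
  invisible(path)
}

#' @rdname muxfish-io
#' @export
readSpotTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.spot_required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required spot column(s): %s",
                 basename(path), paste(miss, collapse = ", ")),
         call. = FALSE)
  SpotTable(df)
}

#' @rdname muxfish-io
#' @param sce a \linkS4class{SingleCellExperiment} with a counts assay.
#' @param dir output directory; writes \code{counts.mtx},
#'   \code{genes.csv}, \code{cells.csv}.
#' @export
writeCountsMTX <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(Matrix::Matrix(as.matrix(m), sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  utils::write.csv(data.frame(gene = rownames(m)),
                   file.path(dir, "genes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(SummarizedExperiment::colData(sce)),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname muxfish-io
#' @export
readCountsMTX <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- utils::read.csv(file.path(dir, "genes.csv"),
                           stringsAsFactors = FALSE)$gene
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, cells$cell_id)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cells, row.names = cells$cell_id),
    metadata = list(genePanel = genes))
}

#' @rdname muxfish-io
#' @param codebook a \linkS4class{Codebook}.
#' @export
writeCodebook <- function(codebook, path) {
  e <- codebook@entries
  obj <- list(n_rounds = codebook@nRounds,
              channels_per_round = codebook@channelsPerRound,
              entries = lapply(seq_len(nrow(e)), function(i)
                list(round = e$round[i], channel = e$channel[i],
                     gene = e$gene[i])))
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
  else yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname muxfish-io
#' @export
readCodebook <- function(path) {
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
  else yaml::read_yaml(path)
  ent <- do.call(rbind, lapply(obj$entries, function(x)
    data.frame(round = as.integer(x$round), channel = as.integer(x$channel),
               gene = as.character(x$gene))))
  Codebook(ent$gene, ent$round, ent$channel,
           nRounds = as.integer(obj$n_rounds),
           channelsPerRound = as.integer(obj$channels_per_round))
}

#' @rdname muxfish-io
#' @param shifts data.frame or matrix with round, dz, dy, dx, score.
#' @export
writeShiftTable <- function(shifts, path) {
  utils::write.csv(as.data.frame(shifts), path, row.names = FALSE)
  invisible(path)
}
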