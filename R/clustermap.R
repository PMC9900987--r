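#' Construct a gene module
#'
#' @param name module name.
#' @param genes character vector of panel genes.
#' @return a \linkS4class{GeneModule}.
#' @export
GeneModule <- function(name, genes) {
  new("GeneModule", name = name, genes = as.character(genes))
}

#' Built-in gene modules
#'
#' The four named co-expression modules used for z > 0 gating:
#' \code{pluripotency} (PouV/Oct4, Nanog, Klf4), \code{pan_ectoderm}
#' (the trio plus Tfap2a and Sox2), \code{neural_crest} (Foxd3, cMyc,
#' Pax7, Snai2, Sox10, Sox9) and \code{neural} (Nestin, MycN, Msi1).
#'
#' @param name module name, or "all" for the full list.
#' @return a \linkS4class{GeneModule}, or a named list of them.
#' @export
builtinModules <- function(name = c("all", "pluripotency", "pan_ectoderm",
                                    "neural_crest", "neural")) {
  name <- match.arg(name)
  mods <- list(
    pluripotency = GeneModule("pluripotency", c("PouV", "Nanog", "Klf4")),
    pan_ectoderm = GeneModule("pan_ectoderm",
                              c("PouV", "Nanog", "Klf4", "Tfap2a", "Sox2")),
    neural_crest = GeneModule("neural_crest",
                              c("Foxd3", "cMyc", "Pax7", "Snai2",
                                "Sox10", "Sox9")),
    neural = GeneModule("neural", c("Nestin", "MycN", "Msi1")))
  if (name == "all") mods else mods[[name]]
}

#' Grouped z-score normalisation
#'
#' Standardises every gene within each normalisation group:
#' z[g, c] = (count[g, c] - mean_group(g)) / sd_group(g), with the
#' population standard deviation (divide by n), so a two-cell group gives
#' z = c(-1, 1). In \code{per_stage} mode the groups are the stages (each
#' pooling all its FOVs, so "high" and "low" are consistent across a
#' section); in \code{cross_stage} mode all cells form a single pooled
#' group, putting stages on a common scale gene by gene. Genes with zero
#' variance inside a group get an all-zero z row segment and are flagged.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a counts assay.
#' @param mode "per_stage" or "cross_stage".
#' @param assay assay name to standardise (default "counts").
#' @param log1p apply log1p before standardising (default FALSE).
#' @param grouping optional explicit factor/vector over cells overriding
#'   the mode's grouping.
#' @return the SCE with an added assay \code{"zscore"} and metadata
#'   entries \code{zscore_mode}, \code{zscore_grouping} and
#'   \code{zero_variance} (genes x groups logical matrix).
#' @export
zscoreCounts <- function(sce, mode = c("per_stage", "cross_stage"),
                         assay = "counts", log1p = FALSE,
                         grouping = NULL) {
  mode <- match.arg(mode)
  m <- SummarizedExperiment::assay(sce, assay)
  m <- as.matrix(m)
  if (log1p) m <- log1p(m)
  if (is.null(grouping)) {
    grouping <- if (mode == "per_stage")
      as.character(SummarizedExperiment::colData(sce)$stage)
    else rep("pooled", ncol(m))
  }
  grouping <- as.character(grouping)
  if (length(grouping) != ncol(m))
    stop("grouping must cover all cells", call. = FALSE)
  if (any(is.na(grouping)))
    stop("grouping contains NA", call. = FALSE)
  groups <- unique(grouping)
  z <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  zerovar <- matrix(FALSE, nrow(m), length(groups),
                    dimnames = list(rownames(m), groups))
  for (g in groups) {
    jj <- which(grouping == g)
    if (!length(jj)) stop("empty normalisation group: ", g, call. = FALSE)
    sub <- m[, jj, drop = FALSE]
    mu <- rowMeans(sub)
    sd_pop <- sqrt(rowMeans((sub - mu)^2))  # population sd (divide by n)
    flat <- sd_pop == 0
    zerovar[, g] <- flat
    sd_pop[flat] <- 1
    z[, jj] <- (sub - mu) / sd_pop
    z[flat, jj] <- 0
  }
  SummarizedExperiment::assay(sce, "zscore") <- z
  S4Vectors::metadata(sce)$zscore_mode <- mode
  S4Vectors::metadata(sce)$zscore_grouping <-
    stats::setNames(grouping, colnames(m))
  S4Vectors::metadata(sce)$zero_variance <- zerovar
  sce
}

#' Hierarchical clustering into subpopulations
#'
#' Agglomerative clustering of cells on their z-scored expression
#' profiles, cut into \code{k} flat clusters. Default distance is
#' correlation (1 - Pearson r between cell profiles) with average
#' linkage, the common choice for expression heatmaps; Ward linkage is
#' restricted to the euclidean metric. Deterministic given its inputs;
#' the display order is the dendrogram leaf order.
#'
#' @param x a \linkS4class{SingleCellExperiment} carrying a
#'   \code{"zscore"} assay, or a genes x cells numeric matrix.
#' @param k number of flat clusters (>= 1).
#' @param metric "correlation" or "euclidean".
#' @param linkage "average", "complete" or "ward" (ward implies
#'   euclidean; combining it with correlation is an error).
#' @return a \linkS4class{ClusterAssignment} (colours assigned from a
#'   default palette; annotate with \code{\link{annotateClusters}}).
#' @export
hierarchicalCluster <- function(x, k,
                                metric = c("correlation", "euclidean"),
                                linkage = c("average", "complete", "ward")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  if (linkage == "ward" && metric != "euclidean")
    stop("ward linkage requires the euclidean metric", call. = FALSE)
  z <- if (is(x, "SummarizedExperiment"))
    as.matrix(SummarizedExperiment::assay(x, "zscore")) else as.matrix(x)
  if (is.null(colnames(z))) colnames(z) <- as.character(seq_len(ncol(z)))
  k <- as.integer(k)
  if (k < 1L || k > ncol(z))
    stop("k must be between 1 and the number of cells", call. = FALSE)
  dd <- if (metric == "euclidean") stats::dist(t(z)) else {
    cc <- suppressWarnings(stats::cor(z))
    cc[!is.finite(cc)] <- 0   # zero-variance profiles: maximal distance
    stats::as.dist(1 - cc)
  }
  hc <- stats::hclust(dd, method = switch(linkage, ward = "ward.D2",
                                          average = "average",
                                          complete = "complete"))
  cl <- stats::cutree(hc, k = k)
  pal <- grDevices::hcl.colors(max(k, 2L), "Dark 3")[seq_len(k)]
  new("ClusterAssignment",
      cluster = stats::setNames(as.integer(cl), colnames(z)),
      hclust = hc,
      leafOrder = colnames(z)[hc$order],
      colors = stats::setNames(pal, as.character(seq_len(k))),
      annotations = stats::setNames(paste("cluster", seq_len(k)),
                                    as.character(seq_len(k))),
      params = list(metric = metric, linkage = linkage, k = k))
}

#' Strict z > 0 co-expression gate
#'
#' Returns the cells whose z-score is strictly positive (above the
#' gene-wise group mean) for every gene of the module — the per-gene
#' passing sets are intersected. Zero is excluded by the strict
#' inequality.
#'
#' @param x SCE with a \code{"zscore"} assay, or a genes x cells matrix
#'   of z-scores.
#' @param module a \linkS4class{GeneModule} (or character vector of
#'   genes, coerced to an unnamed module).
#' @return a \linkS4class{GateResult} with per-stage tallies (stage taken
#'   from colData when available, else a single "all" stratum).
#' @export
gateCoexpression <- function(x, module) {
  if (is.character(module)) module <- GeneModule("custom", module)
  stopifnot(is(module, "GeneModule"))
  stage <- NULL
  z <- if (is(x, "SummarizedExperiment")) {
    stage <- SummarizedExperiment::colData(x)$stage
    as.matrix(SummarizedExperiment::assay(x, "zscore"))
  } else as.matrix(x)
  if (is.null(colnames(z))) colnames(z) <- as.character(seq_len(ncol(z)))
  miss <- setdiff(module@genes, rownames(z))
  if (length(miss))
    stop("module gene(s) absent from the matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  pass <- rep(TRUE, ncol(z))
  for (g in module@genes) pass <- pass & (z[g, ] > 0)
  ids <- colnames(z)[pass]
  if (is.null(stage)) stage <- rep("all", ncol(z))
  tab <- data.frame(stage = as.character(unique(stage)))
  tab$n_cells <- vapply(tab$stage, function(s) sum(stage == s), 0L)
  tab$n_pass <- vapply(tab$stage,
                       function(s) sum(pass & stage == s), 0L)
  tab$fraction <- ifelse(tab$n_cells > 0, tab$n_pass / tab$n_cells, NA)
  new("GateResult", module = module, cellIds = ids, perStage = tab)
}

#' Annotate clusters with labels and colours
#'
#' Attaches free-text annotations (for example "NC stem cells") and
#' display colours to an existing assignment; pure metadata, the
#' clustering and leaf order are untouched.
#'
#' @param assignment a \linkS4class{ClusterAssignment}.
#' @param labels named character, cluster id -> annotation.
#' @param colors optional named character, cluster id -> colour.
#' @return the updated assignment.
#' @export
annotateClusters <- function(assignment, labels, colors = NULL) {
  stopifnot(is(assignment, "ClusterAssignment"))
  present <- as.character(sort(unique(assignment@cluster)))
  unknown <- setdiff(names(labels), present)
  if (length(unknown))
    stop("unknown cluster id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(present, names(labels))
  if (length(missing))
    stop("missing label(s) for cluster(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  assignment@annotations[names(labels)] <- labels
  if (!is.null(colors)) {
    unknown <- setdiff(names(colors), present)
    if (length(unknown))
      stop("unknown cluster id(s) in colors: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    assignment@colors[names(colors)] <- colors
  }
  validObject(assignment)
  assignment
}

#' Clustered expression heatmap
#'
#' Writes a PNG heatmap of the z-score matrix with cells in dendrogram
#' leaf order and a cluster colour bar; a plain base-graphics rendering
#' intended for quick inspection of the subpopulation structure.
#'
#' @param x SCE with a \code{"zscore"} assay or a z-score matrix.
#' @param assignment a \linkS4class{ClusterAssignment} for the same cells.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return invisibly, the leaf order used.
#' @export
writeHeatmap <- function(x, assignment, path, width = 900, height = 600) {
  z <- if (is(x, "SummarizedExperiment"))
    as.matrix(SummarizedExperiment::assay(x, "zscore")) else as.matrix(x)
  ord <- leafOrder(assignment)
  z <- z[, ord, drop = FALSE]
  cl <- assignment@cluster[ord]
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 2, 1), heights = c(1, 9))
  graphics::par(mar = c(0, 6, 1, 1))
  graphics::image(seq_len(ncol(z)), 1, matrix(seq_len(ncol(z)), ncol = 1),
                  col = assignment@colors[as.character(cl)],
                  axes = FALSE, xlab = "", ylab = "")
  graphics::par(mar = c(2, 6, 0, 1))
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  zc <- pmin(pmax(z, -3), 3)
  graphics::image(seq_len(ncol(zc)), seq_len(nrow(zc)), t(zc)[, rev(seq_len(nrow(zc))), drop = FALSE],
                  col = pal, zlim = c(-3, 3), axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(2, at = seq_len(nrow(zc)), labels = rev(rownames(zc)),
                 las = 2, cex.axis = 0.6, tick = FALSE)
  invisible(ord)
}
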