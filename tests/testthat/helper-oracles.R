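# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# median filter oracle: per-voxel neighbourhood sort with reflected borders
oracle_median3d <- function(vol, k = 3L) {
  d <- dim(vol)
  r <- k %/% 2L
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n - i + 1L, i)
  }
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zz <- refl(z + (-r:r), d[1])
    yy <- refl(y + (-r:r), d[2])
    xx <- refl(x + (-r:r), d[3])
    out[z, y, x] <- median(vol[zz, yy, xx])
  }
  out
}

# exhaustive optimal contiguous 2-split of 1-D values by within-cluster SS;
# returns logical: TRUE = member of the upper (signal) block
oracle_split2 <- function(x) {
  o <- order(x)
  s <- x[o]
  n <- length(s)
  best <- Inf
  cut <- 1L
  for (m in 1:(n - 1)) {
    lo <- s[1:m]; hi <- s[(m + 1):n]
    w <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (w < best) { best <- w; cut <- m }
  }
  hi <- logical(n)
  hi[o[(cut + 1):n]] <- TRUE
  hi
}

# naive agglomerative clustering oracle: recompute all pairwise cluster
# distances each step (average or complete linkage, euclidean), return the
# sequence of merged cluster member sets
oracle_agglom <- function(m, linkage = "average") {
  # m: cells in columns
  clusters <- lapply(seq_len(ncol(m)), identity)
  merges <- list()
  dfun <- function(a, b) {
    dd <- outer(a, b, Vectorize(function(i, j)
      sqrt(sum((m[, i] - m[, j])^2))))
    if (linkage == "average") mean(dd) else max(dd)
  }
  while (length(clusters) > 1L) {
    best <- Inf; bi <- c(1L, 2L)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- dfun(clusters[[i]], clusters[[j]])
      if (d < best) { best <- d; bi <- c(j, i) }
    }
    merged <- sort(c(clusters[[bi[1]]], clusters[[bi[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-bi], list(merged))
  }
  merges
}

# greedy matching of detected to true spots within a Chebyshev radius;
# returns c(tp, fn, fp)
oracle_match_spots <- function(det, truth, radius = 2) {
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    if (!nrow(det)) break
    d <- pmax(abs(det$z - truth$z[i]),
              pmax(abs(det$y - truth$y[i]), abs(det$x - truth$x[i])))
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= radius) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fn = nrow(truth) - tp, fp = sum(!used))
}

# adjusted Rand index from the contingency table (closed form)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# intersection-over-union of two voxel sets (linear indices)
iou <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# brute-force per-gene z > 0 set intersection
oracle_gate <- function(z, genes) {
  sets <- lapply(genes, function(g) colnames(z)[z[g, ] > 0])
  Reduce(intersect, sets)
}

# detection of one channel of a simulated FOV, as plain data.frame
detect_fov_channel <- function(sim, fov, r, ch, ...) {
  cfg <- sim$config
  as.data.frame(detectSpots(sim$stacks[[fov]][[r]][, , , ch],
                            sigma = cfg@spotSigma,
                            voxelSize = cfg@voxelSize,
                            fov = fov, round = r, channel = ch, ...))
}
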