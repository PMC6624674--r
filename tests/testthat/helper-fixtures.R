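# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive (all-pairs distances, textbook rank formulas) and never
# call the accelerated implementation paths they check.

makeMask <- function(shape, trueIdx, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     label = "") {
  v <- array(FALSE, dim = shape)
  if (length(trueIdx)) v[trueIdx] <- TRUE
  BinaryMask(v, ImageGeometry(shape, spacing, origin), label = label)
}

cubeMask <- function(shape, lo, hi, spacing = c(1, 1, 1)) {
  v <- array(FALSE, dim = shape)
  v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  BinaryMask(v, ImageGeometry(shape, spacing))
}

randomMask <- function(shape, spacing, pTrue = 0.2, minVoxels = 1) {
  repeat {
    v <- array(runif(prod(shape)) < pTrue, dim = shape)
    if (sum(v) >= minVoxels) break
  }
  BinaryMask(v, ImageGeometry(shape, spacing))
}

# O(n_a * n_b) all-pairs nearest-neighbour distances between mm point sets
bruteNN <- function(from, to) {
  vapply(seq_len(nrow(from)), function(i) {
    d2 <- (to[, 1] - from[i, 1])^2 + (to[, 2] - from[i, 2])^2 +
          (to[, 3] - from[i, 3])^2
    sqrt(min(d2))
  }, numeric(1))
}

# boundary voxel centres by direct 6-neighbour enumeration
bruteBoundary <- function(mask) {
  v <- maskVoxels(mask)
  sh <- dim(v)
  idx <- which(v, arr.ind = TRUE)
  onB <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    any(vapply(nb, function(p) {
      if (any(p < 1) || any(p > sh)) TRUE else !v[p[1], p[2], p[3]]
    }, logical(1)))
  }, logical(1))
  indexToPhysical(geometry(mask), idx[onB, , drop = FALSE])
}

# textbook Spearman: Pearson correlation of average-tie ranks
bruteSpearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

smallMetaFrame <- function(n, zones = NULL, grades = NULL, usable = NULL) {
  data.frame(
    patient_id = sprintf("pt-%03d", seq_len(n)),
    zone = if (is.null(zones)) rep("PZ", n) else zones,
    grade_group = if (is.null(grades)) rep("1", n) else grades,
    observer_id = "obs1",
    ktrans_usable = if (is.null(usable)) rep(TRUE, n) else usable,
    stringsAsFactors = FALSE)
}
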