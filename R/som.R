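#' Batch self-organizing map of time-course profiles
#'
#' Batch SOM on row-standardized profiles: unit prototypes are initialized
#' on the span of the first two principal components (linear initialization;
#' `seed` fixes tie-breaking and any degenerate draws); each epoch assigns
#' every item to its best-matching unit (Euclidean) and updates prototypes
#' as Gaussian-neighborhood-weighted means, with the neighborhood radius
#' decaying linearly from `max(grid)/2` to 0.5 over the epochs. If a
#' neighborhood update would increase the quantization error, a plain batch
#' k-means update is applied for that epoch instead, so the reported
#' quantization error is non-increasing.
#'
#' @param profiles Numeric matrix, items x time points.
#' @param grid Integer vector `c(rows, cols)` of the unit grid.
#' @param epochs Number of batch epochs (default 50).
#' @param seed Integer seed.
#' @return A list with `unit` (per-item unit index), `prototypes` (unit x
#'   time-point matrix, the red/blue unit portraits), `gridCoords`,
#'   `qe` (per-epoch quantization error), `grid`, `method = "som"`, `seed`.
#' @export
somFit <- function(profiles, grid = c(3L, 2L), epochs = 50L, seed = 1L) {
  if (nrow(profiles) == 0L) stop("empty profile matrix")
  x <- standardizeProfiles(profiles)
  nUnits <- prod(grid)
  set.seed(seed)
  coords <- as.matrix(expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2])))

  ## linear initialization on the first two PCs
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ctr <- colMeans(x)
  dir1 <- pc$rotation[, 1] * (if (ncol(pc$rotation) >= 1) sd(pc$x[, 1]) else 1)
  dir2 <- if (ncol(pc$rotation) >= 2 && nrow(x) > 2) {
    pc$rotation[, 2] * sd(pc$x[, 2])
  } else rnorm(ncol(x), sd = 1e-3)
  u <- if (grid[1] > 1) (coords[, 1] - mean(coords[, 1])) / (grid[1] / 2) else rep(0, nUnits)
  v <- if (grid[2] > 1) (coords[, 2] - mean(coords[, 2])) / (grid[2] / 2) else rep(0, nUnits)
  proto <- matrix(ctr, nUnits, ncol(x), byrow = TRUE) +
    outer(u, dir1) + outer(v, dir2) +
    matrix(rnorm(nUnits * ncol(x), sd = 1e-6), nUnits)

  dist2 <- function(p) {
    ## n x nUnits squared distances
    outer(rowSums(x^2), rep(1, nUnits)) - 2 * x %*% t(p) +
      outer(rep(1, nrow(x)), rowSums(p^2))
  }
  gridD2 <- as.matrix(dist(coords))^2
  qeOf <- function(p) mean(apply(dist2(p), 1, min))

  batchUpdate <- function(p, radius) {
    d2 <- dist2(p)
    bmu <- max.col(-d2, ties.method = "first")
    H <- exp(-gridD2 / (2 * radius^2))        # nUnits x nUnits neighborhood
    W <- H[bmu, , drop = FALSE]               # n x nUnits weights
    den <- colSums(W)
    num <- t(W) %*% x
    pNew <- p
    ok <- den > 1e-12
    pNew[ok, ] <- num[ok, , drop = FALSE] / den[ok]
    pNew
  }

  rMax <- max(grid) / 2
  qe <- numeric(epochs)
  qePrev <- qeOf(proto)
  for (ep in seq_len(epochs)) {
    radius <- rMax - (rMax - 0.5) * (ep - 1) / max(1, epochs - 1)
    cand <- batchUpdate(proto, radius)
    if (qeOf(cand) > qePrev + 1e-12) {
      ## monotone fallback: pure batch k-means step (radius -> 0)
      d2 <- dist2(proto)
      bmu <- max.col(-d2, ties.method = "first")
      cand <- proto
      for (uu in unique(bmu))
        cand[uu, ] <- colMeans(x[bmu == uu, , drop = FALSE])
    }
    proto <- cand
    qePrev <- qeOf(proto)
    qe[ep] <- qePrev
  }
  d2 <- dist2(proto)
  unit <- max.col(-d2, ties.method = "first")
  names(unit) <- rownames(profiles)
  list(unit = unit, prototypes = proto, gridCoords = coords, qe = qe,
       grid = grid, method = "som", seed = seed)
}

#' Majority-label purity of SOM units
#'
#' Fraction of items whose unit's majority ground-truth label matches their
#' own label; used to score planted-cluster recovery.
#'
#' @param unit Per-item unit assignment (from [somFit()]).
#' @param truth Per-item true labels.
#' @return Purity in `[0, 1]`.
#' @export
somPurity <- function(unit, truth) {
  agree <- unlist(lapply(split(truth, unit), function(tt) {
    tab <- table(tt)
    rep(names(tab)[which.max(tab)], length(tt)) == tt
  }))
  mean(agree)
}
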