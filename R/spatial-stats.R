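#' Clip log2 activities at zero
#'
#' Activity values below zero (on the log2 scale) are set to zero so that
#' the remaining weight highlights regions of pathway up-regulation; the
#' result is used as the weight vector of the spatial density. A vector with
#' no positive weight is unscorable and flagged via attribute
#' \code{"unscorable"}.
#'
#' @param log2Activity numeric vector (finite).
#' @return non-negative weight vector.
#' @export
clipNonnegative <- function(log2Activity) {
  if (any(!is.finite(log2Activity))) stop("input must be finite")
  w <- pmax(log2Activity, 0)
  if (all(w == 0)) attr(w, "unscorable") <- TRUE
  w
}

# Precompute per-axis Gaussian kernel matrices on a regular grid over the
# bounding box (5% margin). Shared by the weighted and the reference
# density, so divergences reflect the weighting only.
kdeKernels <- function(coords, bandwidth = "scott", gridN = 100,
                       margin = 0.05) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (identical(bandwidth, "scott")) {
    bw <- apply(coords, 2, stats::sd) * n^(-1 / 6)
  } else {
    bw <- rep_len(as.numeric(bandwidth), 2)
  }
  if (any(bw <= 0)) stop("degenerate coordinates: zero bandwidth")
  grid_axis <- function(v) {
    r <- range(v); pad <- margin * diff(r)
    seq(r[1] - pad, r[2] + pad, length.out = gridN)
  }
  gy <- grid_axis(coords[, 1]); gx <- grid_axis(coords[, 2])
  Ky <- exp(-0.5 * (outer(gy, coords[, 1], "-") / bw[1])^2)
  Kx <- exp(-0.5 * (outer(gx, coords[, 2], "-") / bw[2])^2)
  list(Ky = Ky, Kx = Kx, gy = gy, gx = gx, bandwidth = bw, n = n)
}

kdeEvaluate <- function(kernels, weights) {
  d <- kernels$Ky %*% (weights * t(kernels$Kx))
  s <- sum(d)
  if (s <= 0) stop("density sums to zero")
  d / s
}

#' Weighted 2-D kernel density on a grid
#'
#' Gaussian product-kernel density over a regular grid spanning the
#' coordinate bounding box with a 5\% margin; each spot contributes
#' proportionally to its weight and the grid is normalized to sum 1.
#' Bandwidth "scott" applies Scott's rule per axis on all spot coordinates
#' (shared with the uniform-weight reference density).
#'
#' @param coords spots x 2 matrix (y, x).
#' @param weights non-negative spot weights; at least 3 must be positive.
#' @param bandwidth "scott" or a numeric (recycled per axis).
#' @param gridN grid resolution per axis.
#' @return gridN x gridN density matrix summing to 1, with axes attached as
#'   attributes \code{"y"} and \code{"x"}.
#' @export
weightedKDE2D <- function(coords, weights, bandwidth = "scott", gridN = 100) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(weights))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights > 0) < 3)
    stop("unscorable: fewer than 3 spots with positive weight")
  k <- kdeKernels(coords, bandwidth, gridN)
  d <- kdeEvaluate(k, weights)
  attr(d, "y") <- k$gy
  attr(d, "x") <- k$gx
  d
}

#' Spatial divergence of an activity-weighted density
#'
#' Kullback-Leibler divergence D(weighted density || uniform-weight spot
#' density) over grid cells, both floored at \code{epsilon} and renormalized
#' first. Zero when the weights are constant across spots; large when the
#' activity concentrates in a sub-region of the tissue.
#'
#' @inheritParams weightedKDE2D
#' @param epsilon floor applied to both densities before normalization.
#' @return non-negative divergence in nats.
#' @export
spatialKLD <- function(coords, weights, bandwidth = "scott", gridN = 100,
                       epsilon = 1e-12) {
  coords <- as.matrix(coords)
  if (sum(weights > 0) < 3)
    stop("unscorable: fewer than 3 spots with positive weight")
  k <- kdeKernels(coords, bandwidth, gridN)
  kldFromKernels(k, weights, epsilon)
}

kldFromKernels <- function(kernels, weights, epsilon = 1e-12,
                           ref = NULL) {
  p <- kdeEvaluate(kernels, weights)
  q <- if (is.null(ref)) kdeEvaluate(kernels, rep(1, kernels$n)) else ref
  klDiscrete(p, q, epsilon)
}

klDiscrete <- function(p, q, epsilon = 1e-12) {
  p <- pmax(p, epsilon); p <- p / sum(p)
  q <- pmax(q, epsilon); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Permutation p-value for spatial coordination
#'
#' Null model: the weight vector is shuffled across spot positions,
#' destroying any spatial organization while preserving the weight
#' distribution. The p-value uses the add-one estimator
#' p = (1 + #\{permuted KLD >= observed\}) / (nPerm + 1), so its minimum
#' attainable value is 1/(nPerm + 1).
#'
#' @inheritParams spatialKLD
#' @param nPerm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list with \code{kld} (observed) and \code{p}.
#' @export
permutationPvalue <- function(coords, weights, nPerm = 1000, seed = 1L,
                              bandwidth = "scott", gridN = 100,
                              epsilon = 1e-12) {
  if (nPerm < 99) stop("nPerm must be at least 99")
  coords <- as.matrix(coords)
  if (sum(weights > 0) < 3)
    return(list(kld = NA_real_, p = NA_real_, unscorable = TRUE))
  k <- kdeKernels(coords, bandwidth, gridN)
  ref <- kdeEvaluate(k, rep(1, k$n))
  obs <- kldFromKernels(k, weights, epsilon, ref = ref)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(nPerm), function(i) {
      kldFromKernels(k, sample(weights), epsilon, ref = ref) >= obs
    }, logical(1)))
  })
  list(kld = obs, p = (1 + exceed) / (nPerm + 1), unscorable = FALSE)
}

#' Spatial specificity of pathway branches
#'
#' Scores each sink (or each pathway, using the mean of its sinks' clipped
#' log2 activities as the weight) for spatial coordination: the clipped
#' log2 activity weights a kernel density whose divergence from the plain
#' spot density is calibrated by weight permutation. BH adjustment across
#' scorable features; features with q < 0.05 are flagged spatially
#' coordinated.
#'
#' @param activity an \linkS4class{ActivityMatrix}.
#' @param coords spots x 2 coordinate matrix aligned with the activity
#'   columns.
#' @param level "sink" or "pathway".
#' @param nPerm,seed,bandwidth,gridN,epsilon see
#'   \code{\link{permutationPvalue}}.
#' @return data.frame per feature: \code{feature}, \code{pathway_id},
#'   \code{kld}, \code{p}, \code{q}, \code{spatially_coordinated};
#'   unscorable features carry NA p/q.
#' @export
spatialSpecificityTable <- function(activity, coords,
                                    level = c("sink", "pathway"),
                                    nPerm = 1000, seed = 1L,
                                    bandwidth = "scott", gridN = 100,
                                    epsilon = 1e-12) {
  level <- match.arg(level)
  am <- activityAsMatrix(activity)
  idx <- activitySinkIndex(activity, am)
  coords <- as.matrix(coords)
  stopifnot(ncol(am) == nrow(coords))
  la <- log2(am)
  if (level == "sink") {
    feats <- stats::setNames(
      lapply(seq_len(nrow(la)), function(i) pmax(la[i, ], 0)),
      rownames(la) %||% paste0("sink", seq_len(nrow(la))))
    pw <- idx$pathway_id
  } else {
    sp <- split(seq_len(nrow(la)), idx$pathway_id)
    feats <- lapply(sp, function(ix)
      colMeans(pmax(la[ix, , drop = FALSE], 0)))
    pw <- names(feats)
  }
  rows <- mapply(function(w, nm, p_id, i) {
    r <- permutationPvalue(coords, w, nPerm = nPerm, seed = seed + i,
                           bandwidth = bandwidth, gridN = gridN,
                           epsilon = epsilon)
    data.frame(feature = nm, pathway_id = p_id, kld = r$kld, p = r$p,
               stringsAsFactors = FALSE)
  }, feats, names(feats), pw, seq_along(feats) - 1L, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- bhAdjust(out$p[ok])
  out$spatially_coordinated <- !is.na(out$q) & out$q < 0.05
  rownames(out) <- NULL
  out
}
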