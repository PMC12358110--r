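#' Wilcoxon rank-sum test
#'
#' Two-sample Wilcoxon/Mann-Whitney test with midranks for ties. For very
#' small pooled samples the exact conditional distribution of the rank sum
#' is computed by complete enumeration of group assignments (valid with
#' ties); for untied samples below 50 per group the exact distribution is
#' used; otherwise the normal approximation with tie-corrected variance and
#' continuity correction. This mirrors the marker-test convention of
#' single-cell toolkits while staying exact where exactness is cheap.
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with \code{statistic} (the Mann-Whitney U of \code{x}) and
#'   \code{p} (two-sided, in (0, 1]).
#' @export
rankSumTest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(r)
  if (any(ties > 1) && choose(n + m, n) <= 1000) {
    # exact conditional test under ties: enumerate all group assignments
    mu <- n * (n + m + 1) / 2
    obs <- abs(sum(r[seq_len(n)]) - mu)
    sums <- utils::combn(n + m, n, function(ix) sum(r[ix]))
    return(list(statistic = U,
                p = max(mean(abs(sums - mu) >= obs - 1e-9),
                        .Machine$double.xmin)))
  }
  exact <- n < 50 && m < 50 && !any(ties > 1)
  if (exact) {
    p <- if (U > n * m / 2)
      stats::pwilcox(U - 1, n, m, lower.tail = FALSE)
    else
      stats::pwilcox(U, n, m)
    p <- min(1, 2 * p)
  } else {
    mu <- n * m / 2
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    if (sigma2 <= 0) return(list(statistic = U, p = 1))
    z <- U - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = U, p = max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; input order preserved, values
#' capped at 1.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cluster-specific deregulated pathway branches
#'
#' One-vs-all comparison of log2 sink activities: for every cluster and
#' every sink node, in-cluster spots are compared against all other spots
#' with the Wilcoxon rank-sum test; p-values are BH-adjusted within each
#' cluster across all tested sinks. A branch is called at low stringency
#' when q < alpha and |log2 fold change| > \code{lfcLow}, and at high
#' stringency with \code{lfcHigh}; the log2 fold change is the difference of
#' mean log2 activities (in-cluster minus rest).
#'
#' @param activity an \linkS4class{ActivityMatrix} or sinks x spots matrix
#'   of positive activities.
#' @param labels named integer labels over the activity's spots.
#' @param lfcLow,lfcHigh low/high stringency |log2 fc| thresholds.
#' @param alpha FDR level.
#' @param minSpots clusters smaller than this are skipped with a warning.
#' @return data.frame with one row per (cluster, sink): \code{cluster},
#'   \code{pathway_id}, \code{sink}, \code{mean_log2_in},
#'   \code{mean_log2_out}, \code{log2_fc}, \code{p}, \code{q},
#'   \code{significant_low}, \code{significant_high}.
#' @export
clusterBranchMarkers <- function(activity, labels, lfcLow = 0.25,
                                 lfcHigh = 0.5, alpha = 0.05, minSpots = 3) {
  am <- activityAsMatrix(activity)
  idx <- activitySinkIndex(activity, am)
  if (!is.null(names(labels))) {
    if (!all(colnames(am) %in% names(labels)))
      stop("labels missing for some spots")
    labels <- labels[colnames(am)]
  } else if (length(labels) != ncol(am)) {
    stop("labels length does not match number of spots")
  }
  la <- log2(am)
  clusters <- sort(unique(as.integer(labels)))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  res <- list()
  for (cl in clusters) {
    in_cl <- as.integer(labels) == cl
    if (sum(in_cl) < minSpots) {
      warning(sprintf("cluster %d has %d spot(s) (< %d); skipped",
                      cl, sum(in_cl), minSpots))
      next
    }
    stats_cl <- lapply(seq_len(nrow(la)), function(i) {
      x <- la[i, in_cl]; y <- la[i, !in_cl]
      t <- rankSumTest(x, y)
      c(mean(x), mean(y), t$p)
    })
    sm <- do.call(rbind, stats_cl)
    q <- bhAdjust(sm[, 3])
    lfc <- sm[, 1] - sm[, 2]
    res[[length(res) + 1L]] <- data.frame(
      cluster = cl,
      pathway_id = idx$pathway_id, sink = idx$node_id,
      mean_log2_in = sm[, 1], mean_log2_out = sm[, 2],
      log2_fc = lfc, p = sm[, 3], q = q,
      significant_low = q < alpha & abs(lfc) > lfcLow,
      significant_high = q < alpha & abs(lfc) > lfcHigh,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no cluster reached the minimum size")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

activityAsMatrix <- function(activity) {
  if (is(activity, "ActivityMatrix")) as.matrix(assay(activity, "activity"))
  else as.matrix(activity)
}

activitySinkIndex <- function(activity, am) {
  if (is(activity, "ActivityMatrix")) sinkIndex(activity)
  else data.frame(pathway_id = NA_character_,
                  node_id = rownames(am) %||% as.character(seq_len(nrow(am))),
                  label = rownames(am) %||% as.character(seq_len(nrow(am))),
                  stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pathway-level summary of branch calls
#'
#' A pathway is significant in a cluster when at least one of its branches
#' (sink nodes) shows a significant activity change. Also reports the
#' significant-sink ratio and the total activity change (sum over sinks of
#' |log2 fold change|).
#'
#' @param table a \code{\link{clusterBranchMarkers}} result.
#' @param stringency "low" or "high": which significance flag drives counts.
#' @return data.frame per (cluster, pathway): \code{n_sinks},
#'   \code{n_significant_sinks}, \code{significant_ratio},
#'   \code{total_activity_change}, \code{pathway_significant}.
#' @export
summarizePathways <- function(table, stringency = c("low", "high")) {
  stringency <- match.arg(stringency)
  if (!nrow(table)) stop("empty branch test table")
  flag <- if (stringency == "low") table$significant_low else table$significant_high
  key <- interaction(table$cluster, table$pathway_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(table)), key), function(ix) {
    data.frame(
      cluster = table$cluster[ix[1]],
      pathway_id = table$pathway_id[ix[1]],
      n_sinks = length(ix),
      n_significant_sinks = sum(flag[ix]),
      total_activity_change = sum(abs(table$log2_fc[ix])),
      stringsAsFactors = FALSE)
  }))
  out$significant_ratio <- out$n_significant_sinks / out$n_sinks
  out$pathway_significant <- out$n_significant_sinks >= 1
  out <- out[order(out$cluster, out$pathway_id), ]
  rownames(out) <- NULL
  out
}
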