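#' Normalize spot counts
#'
#' Method \code{"lognorm"} (default) scales each spot to the median total
#' count across spots and applies \code{log1p}; method \code{"none"} passes
#' the counts through as dense reals. Pathway signal flow itself consumes
#' ratios (see \code{\link{computeFoldChange}}), which are robust to the
#' choice of monotone normalization.
#'
#' @param expr a \linkS4class{SpotExpression}.
#' @param method "lognorm" or "none".
#' @return a dense genes x spots numeric matrix.
#' @export
normalizeSpots <- function(expr, method = c("lognorm", "none")) {
  stopifnot(is(expr, "SpotExpression"))
  method <- match.arg(method)
  m <- as.matrix(assay(expr, "counts"))
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero))
    stop("spot(s) with zero total count: ",
         paste(utils::head(colnames(m)[zero], 5), collapse = ", "))
  if (method == "none") return(m)
  target <- stats::median(totals)
  log1p(sweep(m, 2, totals / target, "/"))
}

#' Aggregate spots into pseudobulk groups
#'
#' Randomly partitions spots into groups of \code{groupSize}, summing counts
#' and averaging coordinates per group. Pooling roughly ten or more cells
#' per observation stabilises pathway activity estimates on sparse data. A
#' remainder smaller than \code{groupSize / 2} is merged into the last full
#' group; otherwise it is kept as its own (smaller) group.
#'
#' @param expr a \linkS4class{SpotExpression}.
#' @param groupSize spots per pseudobulk group (>= 1).
#' @param seed RNG seed; the partition is deterministic given it.
#' @return a \linkS4class{SpotExpression} of aggregated pseudo-spots with
#'   ids \code{pb1, pb2, ...}. The grand total count is conserved exactly.
#' @export
aggregatePseudobulk <- function(expr, groupSize, seed = 1L) {
  stopifnot(is(expr, "SpotExpression"), groupSize >= 1)
  n <- ncol(expr)
  if (groupSize > n)
    stop(sprintf("groupSize (%d) exceeds the number of spots (%d)", groupSize, n))
  perm <- withr::with_seed(seed, sample.int(n))
  n_full <- n %/% groupSize
  rem <- n %% groupSize
  grp <- rep(seq_len(n_full), each = groupSize)
  if (rem > 0) {
    grp <- c(grp, rep(if (rem >= groupSize / 2) n_full + 1L else n_full, rem))
  }
  grp_of <- integer(n)
  grp_of[perm] <- grp
  m <- assay(expr, "counts")
  f <- factor(grp_of)
  agg <- vapply(levels(f), function(g)
    Matrix::rowSums(m[, grp_of == as.integer(g), drop = FALSE]),
    numeric(nrow(m)))
  co <- spotCoords(expr)
  cd <- colData(expr)
  avg <- function(v) as.vector(tapply(v, f, mean))
  ids <- paste0("pb", levels(f))
  colnames(agg) <- ids
  se <- SummarizedExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(agg, sparse = TRUE),
                                       "CsparseMatrix")),
    colData = S4Vectors::DataFrame(
      coord_y = avg(co[, "y"]), coord_x = avg(co[, "x"]),
      array_row = as.integer(round(avg(cd$array_row))),
      array_col = as.integer(round(avg(cd$array_col))),
      in_tissue = rep(TRUE, length(ids)),
      row.names = ids))
  methods::new("SpotExpression", se)
}

#' Expression fold-change against the global mean
#'
#' Centres each gene on its arithmetic mean over spots:
#' \code{fc(s, g) = (x(s, g) + c) / (mean_s x(s, g) + c)} with pseudocount
#' \code{c}, so 1 is neutral. When the input is the log1p-normalized matrix,
#' set \code{expm1Restore = TRUE} (default) to compute the ratio on the
#' linear scale, which is what multiplicative signal propagation expects.
#' A gene that is zero everywhere gets fold-change 1 in every spot.
#'
#' @param norm genes x spots non-negative matrix (e.g. from
#'   \code{\link{normalizeSpots}}).
#' @param pseudocount non-negative; must be positive if any entry is zero.
#' @param expm1Restore undo a log1p transform before forming ratios.
#' @return genes x spots matrix of strictly positive fold-changes.
#' @export
computeFoldChange <- function(norm, pseudocount = 1, expm1Restore = TRUE) {
  norm <- as.matrix(norm)
  if (any(!is.finite(norm)) || any(norm < 0))
    stop("normalized matrix must be finite and non-negative")
  if (expm1Restore) norm <- expm1(norm)
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount == 0 && any(norm == 0))
    stop("pseudocount = 0 with zero entries present; use a positive pseudocount")
  gm <- rowMeans(norm)
  fc <- (norm + pseudocount) / (gm + pseudocount)
  allzero <- gm == 0
  if (any(allzero)) fc[allzero, ] <- 1
  fc
}
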