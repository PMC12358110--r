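#' Read a Visium-style expression directory
#'
#' Expects the standard triplet \code{matrix.mtx}, \code{features.tsv},
#' \code{barcodes.tsv} (gzipped variants transparently supported) plus a
#' tissue-positions CSV. Both position dialects are auto-detected: the
#' legacy headerless 6-column layout and the headered
#' \code{tissue_positions.csv} layout (barcode, in_tissue, array_row,
#' array_col, pixel row, pixel col). Spots flagged out-of-tissue are
#' dropped; full-resolution pixel (row, col) become coordinates (y, x).
#'
#' @param matrixDir directory with the matrix triplet.
#' @param positionsPath path to the tissue positions CSV.
#' @return a \linkS4class{SpotExpression} restricted to in-tissue spots,
#'   barcodes aligned between matrix and positions.
#' @export
readVisium <- function(matrixDir, positionsPath) {
  find1 <- function(base) {
    for (f in file.path(matrixDir, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing ", base, "(.gz) in ", matrixDir)
  }
  m <- Matrix::readMM(find1("matrix.mtx"))        # genes x spots
  feats <- utils::read.delim(find1("features.tsv"), header = FALSE,
                             colClasses = "character")
  barcodes <- utils::read.delim(find1("barcodes.tsv"), header = FALSE,
                                colClasses = "character")[[1]]
  gene_ids <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  if (nrow(m) != length(gene_ids) || ncol(m) != length(barcodes))
    stop(sprintf("matrix is %d x %d but features/barcodes have %d / %d entries",
                 nrow(m), ncol(m), length(gene_ids), length(barcodes)))

  pos <- readTissuePositions(positionsPath)
  missing_bc <- setdiff(barcodes, pos$barcode)
  if (length(missing_bc))
    stop(sprintf("%d barcode(s) in the matrix are absent from %s (e.g. %s)",
                 length(missing_bc), positionsPath,
                 paste(utils::head(missing_bc, 3), collapse = ", ")))
  pos <- pos[match(barcodes, pos$barcode), ]

  dimnames(m) <- list(make.unique(gene_ids), barcodes)
  keep <- pos$in_tissue == 1
  m <- m[, keep, drop = FALSE]
  pos <- pos[keep, , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(counts = methods::as(m, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(
      coord_y = as.numeric(pos$pxl_row),
      coord_x = as.numeric(pos$pxl_col),
      array_row = as.integer(pos$array_row),
      array_col = as.integer(pos$array_col),
      in_tissue = rep(TRUE, sum(keep)),
      row.names = pos$barcode))
  methods::new("SpotExpression", se)
}

POSITION_COLS <- c("barcode", "in_tissue", "array_row", "array_col",
                   "pxl_row", "pxl_col")

readTissuePositions <- function(path) {
  first <- readLines(path, n = 1)
  headered <- grepl("barcode", first, ignore.case = TRUE)
  pos <- utils::read.csv(path, header = headered,
                         colClasses = c("character", rep("numeric", 5)))
  if (ncol(pos) < 6) stop("tissue positions file needs 6 columns, got ", ncol(pos))
  names(pos)[1:6] <- POSITION_COLS
  pos
}

#' Write a SpotExpression as a Visium-style directory
#'
#' Counterpart of \code{\link{readVisium}}: writes the uncompressed matrix
#' triplet and a headered tissue positions CSV. Round-trips counts and
#' coordinates bit-exactly.
#'
#' @param expr a \linkS4class{SpotExpression}.
#' @param dir output directory (created); the positions file is written as
#'   \code{dir/tissue_positions.csv}.
#' @return \code{dir}, invisibly.
#' @export
writeVisium <- function(expr, dir) {
  stopifnot(is(expr, "SpotExpression"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- assay(expr, "counts")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = rownames(expr), name = rownames(expr),
               type = "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(expr), file.path(dir, "barcodes.tsv"))
  cd <- colData(expr)
  pos <- data.frame(
    barcode = colnames(expr),
    in_tissue = as.integer(cd$in_tissue),
    array_row = cd$array_row,
    array_col = cd$array_col,
    pxl_row_in_fullres = cd$coord_y,
    pxl_col_in_fullres = cd$coord_x)
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
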