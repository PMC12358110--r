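#' Run the full spatial pathway-activity pipeline
#'
#' Orchestrates read, normalization, fold-change, pathway signal flow,
#' clustering, branch statistics, spatial coordination and border crosstalk,
#' writing each stage's table plus a manifest (config echo, seeds, stage
#' outputs, per-stage counts) under \code{outDir}. Stages downstream of the
#' activity matrix can be switched off.
#'
#' @param config list (or path to a YAML file) with entries:
#'   \code{visium_dir}, \code{positions} (defaults to
#'   \code{visium_dir/tissue_positions.csv}), \code{pathway_dir} (directory
#'   of native-format pathway subdirectories and/or \code{.xml} KGML
#'   files), \code{out_dir}; optional \code{labels} (TSV of precomputed
#'   clusters), \code{normalization} ("lognorm"/"none"), \code{pseudocount},
#'   \code{n_pcs}, \code{k_neighbors}, \code{resolution}, \code{lfc_low},
#'   \code{lfc_high}, \code{alpha}, \code{grid_n}, \code{n_perm},
#'   \code{min_group}, \code{seed}, and logical stage switches
#'   \code{do_clustering}, \code{do_markers}, \code{do_spatial},
#'   \code{do_border}.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(normalization = "lognorm", pseudocount = 1,
                   n_pcs = 30, k_neighbors = 20, resolution = 1.0,
                   lfc_low = 0.25, lfc_high = 0.5, alpha = 0.05,
                   grid_n = 100, n_perm = 1000, min_group = 10,
                   seed = 1L, do_clustering = TRUE, do_markers = TRUE,
                   do_spatial = TRUE, do_border = TRUE)
  config <- utils::modifyList(defaults, config)
  for (field in c("visium_dir", "pathway_dir", "out_dir"))
    if (is.null(config[[field]])) stop("config is missing '", field, "'")
  if (is.null(config$positions))
    config$positions <- file.path(config$visium_dir, "tissue_positions.csv")
  if (!dir.exists(config$visium_dir)) stop("visium_dir does not exist")
  if (!dir.exists(config$pathway_dir)) stop("pathway_dir does not exist")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, stages = list(), counts = list())
  emit <- function(stage, file) {
    manifest$stages[[stage]] <<- file
  }

  expr <- readVisium(config$visium_dir, config$positions)
  manifest$counts$spots_read <- ncol(expr)
  manifest$counts$genes_read <- nrow(expr)

  pathways <- loadPathwayDir(config$pathway_dir)
  manifest$counts$pathways <- length(pathways)
  manifest$counts$edges_removed <-
    sum(vapply(pathways, function(g) nrow(removedEdges(g)), integer(1)))

  norm <- normalizeSpots(expr, config$normalization)
  fc <- computeFoldChange(norm, config$pseudocount,
                          expm1Restore = config$normalization == "lognorm")
  utils::write.table(data.frame(gene = rownames(fc), fc, check.names = FALSE),
                     file.path(out, "fold_change.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("fold_change", "fold_change.tsv")

  activity <- runPSF(fc, pathways)
  writeActivityMatrix(activity, file.path(out, "activity.tsv"))
  emit("activity", "activity.tsv")
  manifest$counts$sinks <- nrow(activity)

  labels <- NULL
  if (!is.null(config$labels)) {
    labels <- readClusterLabels(config$labels)
  } else if (isTRUE(config$do_clustering)) {
    labels <- clusterFeatures(t(log2(assay(activity, "activity"))),
                              nPCs = config$n_pcs,
                              kNeighbors = config$k_neighbors,
                              resolution = config$resolution,
                              seed = config$seed)
    writeClusterLabels(labels, file.path(out, "clusters.tsv"))
    emit("clusters", "clusters.tsv")
    manifest$counts$clusters <- length(unique(labels))
  }

  markers <- pathway_summary <- NULL
  if (isTRUE(config$do_markers) && !is.null(labels) &&
      length(unique(labels)) >= 2) {
    markers <- clusterBranchMarkers(activity, labels,
                                    lfcLow = config$lfc_low,
                                    lfcHigh = config$lfc_high,
                                    alpha = config$alpha)
    utils::write.table(markers, file.path(out, "branch_markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("branch_markers", "branch_markers.tsv")
    manifest$counts$sinks_tested <- nrow(markers)
    pathway_summary <- summarizePathways(markers, "low")
    utils::write.table(pathway_summary, file.path(out, "pathway_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("pathway_summary", "pathway_summary.tsv")
  }

  spatial <- NULL
  if (isTRUE(config$do_spatial)) {
    spatial <- spatialSpecificityTable(activity, spotCoords(expr),
                                       level = "sink",
                                       nPerm = config$n_perm,
                                       seed = config$seed,
                                       gridN = config$grid_n)
    utils::write.table(spatial, file.path(out, "spatial_specificity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("spatial_specificity", "spatial_specificity.tsv")
    manifest$counts$spatially_coordinated <- sum(spatial$spatially_coordinated)
  }

  border <- NULL
  if (isTRUE(config$do_border) && !is.null(labels) &&
      length(unique(labels)) >= 2) {
    border <- borderCrosstalk(activity, labels, spotCoords(expr), pathways,
                              alpha = config$alpha,
                              minGroup = config$min_group)
    utils::write.table(border$groups, file.path(out, "border_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("border_groups", "border_groups.tsv")
    utils::write.table(border$links, file.path(out, "lr_links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("lr_links", "lr_links.tsv")
    manifest$counts$lr_links <- nrow(border$links)
  }

  manifest$package_version <- as.character(utils::packageVersion("SpatialPSF"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(expr = expr, pathways = pathways, fold_change = fc,
                 activity = activity, labels = labels, markers = markers,
                 pathway_summary = pathway_summary, spatial = spatial,
                 border = border, manifest = manifest))
}

#' Load all pathways from a directory
#'
#' Accepts a mixture of KGML files (\code{*.xml}) and native-format
#' subdirectories (containing \code{nodes.tsv}/\code{edges.tsv}); every
#' pathway is preprocessed (cycles broken, roles assigned).
#'
#' @param dir pathway directory.
#' @return named list of \linkS4class{PathwayGraph}s.
#' @export
loadPathwayDir <- function(dir) {
  xmls <- list.files(dir, pattern = "\\.xml$", full.names = TRUE)
  subdirs <- Filter(function(d) file.exists(file.path(d, "nodes.tsv")),
                    list.dirs(dir, recursive = TRUE))
  graphs <- c(lapply(xmls, parseKGML), lapply(subdirs, readPathwayTables))
  if (!length(graphs)) stop("no pathways found in ", dir)
  graphs <- lapply(graphs, preprocessPathway)
  names(graphs) <- vapply(graphs, pathwayId, character(1))
  graphs
}

#' Simulate a dataset to disk
#'
#' Thin wrapper for the command-line \code{simulate} subcommand: generates
#' either a generic multi-cluster dataset or the ligand-receptor border
#' scenario and writes it through the standard file interfaces.
#'
#' @param outDir output directory.
#' @param scenario "generic" or "lr".
#' @param seed RNG seed.
#' @param nSide lattice side.
#' @param clusters regions (generic scenario).
#' @param nPathways pathways to generate (generic scenario).
#' @return the dataset list, invisibly.
#' @export
simulateDataset <- function(outDir, scenario = c("generic", "lr"), seed = 1L,
                            nSide = 16, clusters = 3, nPathways = 3) {
  scenario <- match.arg(scenario)
  if (scenario == "lr") {
    ds <- makeLRScenario(seed = seed, nSide = nSide)
  } else {
    pws <- lapply(seq_len(nPathways), function(i)
      makePathway(8, edgeProb = 0.35, seed = seed * 100L + i,
                  pathwayId = sprintf("SYN%03d", i)))
    ds <- makeSpatialDataset(nSide = nSide, clusters = clusters,
                             pathways = pws, seed = seed)
    ds$pathways <- pws
  }
  writeSyntheticDataset(ds, outDir)
  invisible(ds)
}
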