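# End-to-end orchestration: the functions behind the command-line script
# (inst/scripts/blockgraph-cli). Machine-readable outputs go to files;
# progress notes go to stderr via message().

#' Assemble a full run configuration
#'
#' @param msaPath path to the aligned FASTA input.
#' @param objective objective name.
#' @param alpha vertical-block threshold or \code{"disabled"}.
#' @param decomposition \code{"row-maximal"} or \code{"complete"}.
#' @param q,delta,p objective parameters (see [objectiveSpec()]).
#' @param k seed length for the metrics.
#' @param depthThreshold node-depth fraction for the metrics.
#' @param seed solver seed (the default backend is deterministic).
#' @param timeLimit per-window solver time limit (seconds).
#' @param outDir output directory.
#' @return a list of class \code{"blockgraphConfig"}.
#' @export
runConfig <- function(msaPath, objective = "blocks", alpha = "disabled",
                      decomposition = "row-maximal", q = 20, delta = 1000,
                      p = 0.11, k = 20L, depthThreshold = 0.11, seed = 0L,
                      timeLimit = 600, outDir = ".") {
    structure(list(msaPath = msaPath, objective = objective, alpha = alpha,
                   decomposition = decomposition, q = q, delta = delta,
                   p = p, k = k, depthThreshold = depthThreshold,
                   seed = seed, timeLimit = timeLimit, outDir = outDir),
              class = "blockgraphConfig")
}

#' Run the whole pipeline on one alignment
#'
#' read MSA -> build instances -> solve each free window -> merge with the
#' forced vertical blocks -> build graph -> post-process -> write GFA +
#' metrics. Writes \code{graph.gfa}, \code{metrics.json},
#' \code{metrics.tsv}, \code{solve_report.json} and \code{config.json}
#' into \code{config$outDir}.
#'
#' @param config a [runConfig()] list.
#' @return invisibly, a list with the \code{cover}, the post-processed
#'   \code{graph}, the \code{metrics} and the output \code{paths}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "blockgraphConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    msa <- readMsa(config$msaPath)
    message(sprintf("[blockgraph] MSA: %d rows x %d columns", nrow(msa),
                    ncol(msa)))
    obj <- objectiveSpec(config$objective, q = config$q,
                         delta = config$delta, p = config$p)
    cover <- solveMsaCover(msa, obj, alpha = config$alpha,
                           strategy = config$decomposition,
                           timeLimit = config$timeLimit,
                           solverSeed = config$seed)
    message(sprintf("[blockgraph] cover: %d blocks, objective %s = %g%s",
                    length(cover@blocks), config$objective,
                    cover@objectiveValue,
                    if (cover@optimal) " (optimal)" else " (incumbent)"))
    graph <- postprocessGraph(buildGraph(msa, cover))
    metrics <- computeGraphMetrics(graph, k = config$k,
                                   depthThreshold = config$depthThreshold)
    message(sprintf("[blockgraph] graph: %d nodes, %d arcs",
                    length(graph@nodeIds), nrow(graph@arcs)))
    paths <- list(gfa = file.path(config$outDir, "graph.gfa"),
                  metricsJson = file.path(config$outDir, "metrics.json"),
                  metricsTsv = file.path(config$outDir, "metrics.tsv"),
                  report = file.path(config$outDir, "solve_report.json"),
                  config = file.path(config$outDir, "config.json"))
    writeGfa(graph, paths$gfa)
    jsonlite::write_json(metrics, paths$metricsJson, auto_unbox = TRUE,
                         digits = NA)
    utils::write.table(as.data.frame(metrics[1:5]), paths$metricsTsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(objective = config$objective,
                              value = cover@objectiveValue,
                              status = if (cover@optimal) "optimal"
                                       else "incumbent",
                              n_blocks = length(cover@blocks),
                              seed = config$seed),
                         paths$report, auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                         digits = NA)
    invisible(list(cover = cover, graph = graph, metrics = metrics,
                   paths = paths))
}

#' Breakpoint report for an alignment
#'
#' @param msaPath aligned FASTA input.
#' @param out output TSV path (columns \code{alpha},
#'   \code{longest_free_window}), or NULL to return the table.
#' @return the breakpoint data frame (invisibly when written).
#' @export
cmdBreakpoints <- function(msaPath, out = NULL) {
    bp <- alphaBreakpoints(readMsa(msaPath))
    if (is.null(out)) return(bp)
    utils::write.table(bp, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(bp)
}

#' Block dump for an alignment
#'
#' Enumerates maximal blocks (and, optionally, their decomposition) and
#' writes the tab-separated block table.
#'
#' @param msaPath aligned FASTA input.
#' @param strategy NULL for maximal blocks only, else a decomposition
#'   strategy name.
#' @param minRows minimum rows of enumerated maximal blocks.
#' @param out output TSV path, or NULL to return the table.
#' @return the block data frame (invisibly when written).
#' @export
cmdBlocks <- function(msaPath, strategy = NULL, minRows = 2L, out = NULL) {
    msa <- readMsa(msaPath)
    maximal <- enumerateMaximalBlocks(msa, minRows = minRows)
    if (is.null(strategy)) {
        blocks <- maximal
        origin <- rep("maximal", length(blocks))
    } else {
        blocks <- decomposeAll(msa, maximal, strategy)
        keys <- vapply(maximal, blockKey, character(1L))
        origin <- ifelse(vapply(blocks, blockKey, character(1L)) %in% keys,
                         "maximal",
                         if (strategy == "complete") "complete-dec"
                         else "rowmax-dec")
    }
    df <- blocksToTable(msa, blocks, path = out, origin = origin)
    if (is.null(out)) df else invisible(df)
}

#' Metrics of an existing GFA file
#'
#' @param gfaPath GFA1 file with P lines (as written by [writeGfa()]).
#' @param k seed length.
#' @param depthThreshold node-depth fraction.
#' @param out output JSON path, or NULL to return the metrics list.
#' @return the metrics list (invisibly when written).
#' @export
cmdMetrics <- function(gfaPath, k = 20L, depthThreshold = 0.11,
                       out = NULL) {
    metrics <- computeGraphMetrics(readGfa(gfaPath), k = k,
                                   depthThreshold = depthThreshold)
    if (is.null(out)) return(metrics)
    jsonlite::write_json(metrics, out, auto_unbox = TRUE, digits = NA)
    invisible(metrics)
}
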