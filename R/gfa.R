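# GFA1 serialization and the graph evaluation metrics.

#' Write a variation graph as GFA1
#'
#' Emits an H line (\code{VN:Z:1.0}), one S line per node (sorted by id),
#' one L line per arc with overlap \code{0M} (sorted by from, to), and one
#' P line per walk in input-row order, all orientations \code{+}, cigars
#' \code{*}. Duplicate walk names get a numeric suffix so path names stay
#' unique.
#'
#' @param graph a post-processed [VariationGraph].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeGfa <- function(graph, path) {
    o <- order(graph@nodeIds)
    s <- sprintf("S\t%d\t%s", graph@nodeIds[o], graph@labels[o])
    l <- character()
    if (nrow(graph@arcs)) {
        a <- graph@arcs[order(graph@arcs[, 1L], graph@arcs[, 2L]), ,
                        drop = FALSE]
        l <- sprintf("L\t%d\t+\t%d\t+\t0M", a[, 1L], a[, 2L])
    }
    nm <- graph@walkIds
    if (anyDuplicated(nm)) nm <- make.unique(nm, sep = "_")
    p <- vapply(seq_along(graph@walks), function(i)
        sprintf("P\t%s\t%s\t*", nm[i],
                paste0(graph@walks[[i]], "+", collapse = ",")),
        character(1L))
    writeLines(c("H\tVN:Z:1.0", s, l, p), path)
    invisible(path)
}

#' Read a GFA1 file back into a variation graph
#'
#' Parses S, L and P lines as written by [writeGfa()] (P segments must all
#' be forward-oriented).
#'
#' @param path a GFA1 file.
#' @return a [VariationGraph].
#' @export
readGfa <- function(path) {
    lines <- readLines(path)
    tag <- substr(lines, 1L, 1L)
    sParts <- strsplit(lines[tag == "S"], "\t", fixed = TRUE)
    ids <- vapply(sParts, function(x) as.integer(x[2L]), integer(1L))
    labels <- vapply(sParts, function(x) x[3L], character(1L))
    lParts <- strsplit(lines[tag == "L"], "\t", fixed = TRUE)
    arcs <- if (length(lParts))
        cbind(vapply(lParts, function(x) as.integer(x[2L]), integer(1L)),
              vapply(lParts, function(x) as.integer(x[4L]), integer(1L)))
    else matrix(integer(), 0L, 2L)
    pParts <- strsplit(lines[tag == "P"], "\t", fixed = TRUE)
    walkIds <- vapply(pParts, function(x) x[2L], character(1L))
    walks <- lapply(pParts, function(x) {
        segs <- strsplit(x[3L], ",", fixed = TRUE)[[1L]]
        if (!all(grepl("\\+$", segs)))
            stop("only forward-oriented path segments are supported")
        as.integer(sub("\\+$", "", segs))
    })
    new("VariationGraph", nodeIds = ids, labels = labels, arcs = arcs,
        walks = walks, walkIds = walkIds)
}

kmerSet <- function(label, k) {
    n <- nchar(label)
    if (n < k) return(character())
    unique(substring(label, seq_len(n - k + 1L), k:n))
}

#' Evaluation metrics of a variation graph
#'
#' The four summary statistics used to compare construction settings:
#' number of nodes, total (ungapped) label length, number of potential
#' k-mer seeds, and node-depth counts. Potential seeds are counted per
#' occurrence position within labels (\code{seedMode = "positions"}: sum of
#' \code{max(0, |label| - k + 1)}) or as the number of distinct k-mers
#' appearing in at least one label (\code{"distinct"}).
#'
#' @param graph a post-processed [VariationGraph].
#' @param k seed length (default 20).
#' @param depthThreshold fraction in (0, 1]; a node counts toward
#'   \code{depth_fraction_nodes} when at least
#'   \code{ceiling(depthThreshold * #walks)} walks traverse it.
#' @param seedMode \code{"positions"} (default) or \code{"distinct"}.
#' @return named list: \code{n_nodes}, \code{total_label_length},
#'   \code{potential_seeds}, \code{depth_fraction_nodes},
#'   \code{all_sequences_nodes}, plus the parameters used.
#' @examples
#' g <- postprocessGraph(buildGraph(runningExample(),
#'                                  solveMsaCover(runningExample(), alpha = 2)))
#' computeGraphMetrics(g, k = 3)
#' @export
computeGraphMetrics <- function(graph, k = 20L, depthThreshold = 0.11,
                                seedMode = c("positions", "distinct")) {
    seedMode <- match.arg(seedMode)
    stopifnot(k >= 1L, depthThreshold > 0, depthThreshold <= 1)
    lens <- nchar(graph@labels)
    seeds <- if (seedMode == "positions")
        sum(pmax(0L, lens - as.integer(k) + 1L))
    else length(unique(unlist(lapply(graph@labels, kmerSet, k = k))))
    nWalks <- length(graph@walks)
    visits <- table(factor(unlist(lapply(graph@walks, unique)),
                           levels = graph@nodeIds))
    need <- ceiling(depthThreshold * nWalks)
    list(n_nodes = length(graph@nodeIds),
         total_label_length = sum(lens),
         potential_seeds = as.integer(seeds),
         depth_fraction_nodes = sum(visits >= need),
         all_sequences_nodes = sum(visits == nWalks),
         k = as.integer(k), depth_threshold = depthThreshold,
         seed_mode = seedMode)
}
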