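# Downstream analytics on directed regulatory networks. All functions accept
# either a SignedNetwork/InferredNetwork or a plain edge data.frame with
# columns regulator/target (extra columns ignored).

.asEdges <- function(net) {
    if (is(net, "SignedNetwork")) return(edgeList(net))
    if (is.data.frame(net)) {
        stopifnot(all(c("regulator", "target") %in% names(net)))
        return(net)
    }
    stop("unsupported network representation: ", class(net)[1])
}

.netNodes <- function(net, edges) {
    if (is(net, "SignedNetwork")) nodeIds(net)
    else sort(unique(c(edges$regulator, edges$target)), method = "radix")
}

#' Degree summary of a directed network
#'
#' Per-node in- and out-degree plus the network's average degree, defined as
#' |edges| / |nodes| (the convention under which a 56-node, 230-edge network
#' has average degree 4 and a 68-node, 98-edge one has 1.4). Reported raw
#' and rounded to one decimal.
#'
#' @param net a [SignedNetwork-class], [InferredNetwork-class], or edge
#'   data.frame (columns regulator, target).
#' @param nodes optional node universe (to count isolated nodes when
#'   \code{net} is an edge data.frame).
#' @return list: \code{perNode} data.frame (node, inDegree, outDegree),
#'   \code{nNodes}, \code{nEdges}, \code{averageDegree},
#'   \code{averageDegreeRounded}.
#' @examples
#' el <- data.frame(regulator = "a", target = c("b", "c"))
#' degreeSummary(el)$averageDegree  # 2/3
#' @export
degreeSummary <- function(net, nodes = NULL) {
    edges <- .asEdges(net)
    if (is.null(nodes)) nodes <- .netNodes(net, edges)
    if (!length(nodes)) stop("network has no nodes")
    inDeg <- table(factor(edges$target, levels = nodes))
    outDeg <- table(factor(edges$regulator, levels = nodes))
    perNode <- data.frame(node = nodes,
                          inDegree = as.integer(inDeg),
                          outDegree = as.integer(outDeg),
                          stringsAsFactors = FALSE)
    avg <- nrow(edges) / length(nodes)
    list(perNode = perNode, nNodes = length(nodes), nEdges = nrow(edges),
         averageDegree = avg, averageDegreeRounded = round(avg, 1))
}

#' Identify hub nodes by in-degree
#'
#' Nodes whose in-degree is strictly greater than \code{multiplier} times
#' the network's average degree (|edges|/|nodes|): multiplier 1 gives the
#' "higher in-degree than average" set, multiplier 2 the "twice the average"
#' set. Sorted by in-degree descending, ties lexicographic.
#'
#' @inheritParams degreeSummary
#' @param multiplier nonnegative threshold multiplier.
#' @return data.frame (node, inDegree) of hubs.
#' @export
identifyHubs <- function(net, multiplier = 1, nodes = NULL) {
    stopifnot(multiplier >= 0)
    ds <- degreeSummary(net, nodes)
    thr <- multiplier * ds$averageDegree
    hubs <- ds$perNode[ds$perNode$inDegree > thr, c("node", "inDegree")]
    hubs <- hubs[order(-hubs$inDegree, hubs$node, method = "radix"), ,
                 drop = FALSE]
    rownames(hubs) <- NULL
    hubs
}

#' Enumerate directed simple paths between two genes
#'
#' All directed paths from \code{source} to \code{target} that repeat no
#' node, up to \code{maxLength} edges, in deterministic lexicographic order
#' of the node sequence. Backed by \code{igraph::all_simple_paths}. A query
#' with \code{source == target} returns an empty list with a warning (cycles
#' are out of scope).
#'
#' @inheritParams degreeSummary
#' @param source,target node identifiers present in the network.
#' @param maxLength maximum path length in edges (default 10, generous for
#'   regulatory cascades).
#' @return list of character vectors (node sequences, inclusive).
#' @examples
#' el <- data.frame(regulator = c("a", "b"), target = c("b", "c"))
#' findDirectedPaths(el, "a", "c")  # list(c("a","b","c"))
#' @export
findDirectedPaths <- function(net, source, target, maxLength = 10,
                              nodes = NULL) {
    edges <- .asEdges(net)
    if (is.null(nodes)) nodes <- .netNodes(net, edges)
    if (identical(source, target)) {
        warning("source equals target: returning no paths (cycles out of scope)")
        return(list())
    }
    if (!nrow(edges)) return(list())
    if (!source %in% nodes) stop("source node not in network: ", source)
    if (!target %in% nodes) stop("target node not in network: ", target)
    g <- igraph::graph_from_data_frame(
        edges[, c("regulator", "target")], directed = TRUE,
        vertices = data.frame(name = nodes))
    paths <- igraph::all_simple_paths(g, from = source, to = target,
                                      mode = "out", cutoff = maxLength)
    paths <- lapply(paths, function(p) igraph::as_ids(p))
    keys <- vapply(paths, paste, character(1), collapse = "")
    paths[order(keys, method = "radix")]
}

#' Merge a gene regulatory network with protein-protein interactions
#'
#' Builds a two-layer [CombinedNetwork-class]: the GRN's gene nodes with
#' their directed regulatory edges, plus protein nodes with undirected
#' interaction edges. Interaction endpoints given in gene space are
#' translated to protein identifiers through \code{geneProteinMap}.
#' Duplicate edges within a layer (including A-B vs B-A interactions) are
#' collapsed and counted. Gene and protein identifier spaces must be
#' disjoint; collisions are an error.
#'
#' @param grn a [SignedNetwork-class]/[InferredNetwork-class] or regulatory
#'   edge data.frame (regulator, target, optional weight).
#' @param ppi data.frame of undirected interactions, columns \code{a},
#'   \code{b} (protein — or gene, when mapped — identifiers).
#' @param geneProteinMap optional data.frame (gene, protein) used to rename
#'   interaction endpoints from gene to protein space.
#' @return A [CombinedNetwork-class]; \code{@metadata$duplicates} counts
#'   collapsed edges per layer.
#' @export
mergePpi <- function(grn, ppi, geneProteinMap = NULL) {
    edges <- .asEdges(grn)
    genes <- .netNodes(grn, edges)
    stopifnot(is.data.frame(ppi))
    if (nrow(ppi)) stopifnot(all(c("a", "b") %in% names(ppi)))
    a <- as.character(ppi$a)
    b <- as.character(ppi$b)
    if (!is.null(geneProteinMap)) {
        stopifnot(all(c("gene", "protein") %in% names(geneProteinMap)))
        if (anyDuplicated(geneProteinMap$gene))
            stop("gene -> protein map collisions: ",
                 paste(unique(geneProteinMap$gene[
                     duplicated(geneProteinMap$gene)]), collapse = ", "))
        trans <- stats::setNames(as.character(geneProteinMap$protein),
                                 as.character(geneProteinMap$gene))
        a <- ifelse(a %in% names(trans), trans[a], a)
        b <- ifelse(b %in% names(trans), trans[b], b)
    }
    proteins <- sort(unique(c(a, b)), method = "radix")
    collision <- intersect(genes, proteins)
    if (length(collision))
        stop("identifiers in both gene and protein space: ",
             paste(collision, collapse = ", "))
    reg <- data.frame(from = edges$regulator, to = edges$target,
                      weight = if ("weight" %in% names(edges)) edges$weight
                               else NA_real_,
                      provenance = "regulatory", stringsAsFactors = FALSE)
    dupReg <- duplicated(reg[, c("from", "to")])
    inter <- if (length(a))
        data.frame(a = pmin(a, b), b = pmax(a, b),
                   provenance = "interaction", stringsAsFactors = FALSE)
    else data.frame(a = character(0), b = character(0),
                    provenance = character(0), stringsAsFactors = FALSE)
    dupInt <- if (nrow(inter)) duplicated(inter[, c("a", "b")]) else logical(0)
    reg <- reg[!dupReg, , drop = FALSE]
    inter <- inter[!dupInt, , drop = FALSE]
    reg <- reg[order(reg$from, reg$to, method = "radix"), , drop = FALSE]
    if (nrow(inter))
        inter <- inter[order(inter$a, inter$b, method = "radix"), ,
                       drop = FALSE]
    rownames(reg) <- rownames(inter) <- NULL
    new("CombinedNetwork", genes = genes, proteins = proteins,
        regulatoryEdges = reg, interactionEdges = inter,
        metadata = list(duplicates = c(regulatory = sum(dupReg),
                                       interaction = sum(dupInt))))
}

#' Subcellular localization summary
#'
#' Tabulates an annotation category (localization by default) over a gene
#' list: counts partition the input, and percentages (count / total x 100,
#' one decimal) sum to 100 up to rounding. Genes missing from the annotation
#' table fall in the \code{"unknown"} category.
#'
#' @param genes character vector of gene identifiers (nonempty).
#' @param annotations data.frame with columns \code{gene} and
#'   \code{localization}.
#' @return data.frame (category, count, percentage) sorted by count
#'   descending then category.
#' @examples
#' ann <- data.frame(gene = c("a", "b"), localization = c("plasma", "nucleus"))
#' localizationSummary(c("a", "b", "c"), ann)
#' @export
localizationSummary <- function(genes, annotations) {
    if (!length(genes)) stop("empty gene list")
    stopifnot(is.data.frame(annotations),
              all(c("gene", "localization") %in% names(annotations)))
    loc <- stats::setNames(as.character(annotations$localization),
                           as.character(annotations$gene))
    cat <- ifelse(genes %in% names(loc), loc[genes], "unknown")
    cat[is.na(cat) | !nzchar(cat)] <- "unknown"
    counts <- table(cat)
    out <- data.frame(category = names(counts),
                      count = as.integer(counts),
                      stringsAsFactors = FALSE)
    out$percentage <- round(100 * out$count / length(genes), 1)
    out <- out[order(-out$count, out$category, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' qPCR relative quantification (2^-ddCt)
#'
#' Standard comparative-Ct quantification: per group, dCt = Ct(target) -
#' Ct(reference); ddCt = dCt(treated) - dCt(control); the relative quantity
#' is \eqn{RQ = 2^{-\Delta\Delta Ct}}. Vectors of replicate Ct values are
#' averaged per group. Strictly decreasing in ddCt: each extra cycle of
#' relative delay halves the quantity.
#'
#' @param targetTreated,referenceTreated,targetControl,referenceControl
#'   numeric Ct values (cycles, > 0); replicates allowed.
#' @return numeric scalar RQ.
#' @examples
#' computeRq(24, 20, 25, 20)  # one cycle earlier in treated: RQ = 2
#' @export
computeRq <- function(targetTreated, referenceTreated, targetControl,
                      referenceControl) {
    cts <- list(targetTreated = targetTreated,
                referenceTreated = referenceTreated,
                targetControl = targetControl,
                referenceControl = referenceControl)
    for (nm in names(cts)) {
        v <- cts[[nm]]
        if (!length(v) || any(is.na(v)))
            stop("missing Ct value in ", nm)
        if (any(v <= 0)) stop("Ct values must be positive in ", nm)
    }
    dTreated <- mean(targetTreated) - mean(referenceTreated)
    dControl <- mean(targetControl) - mean(referenceControl)
    2^(-(dTreated - dControl))
}
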