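#' Accessors for stepnet classes
#'
#' @param x a stepnet object.
#' @return \code{nodeIds}: character vector of node identifiers.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setMethod("nodeIds", "SignedNetwork", function(x) x@nodeIds)

#' @rdname accessors
#' @return \code{weightMatrix}: the square coefficient matrix A.
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname accessors
#' @export
setMethod("weightMatrix", "SignedNetwork", function(x) x@weights)

#' @rdname accessors
#' @return \code{edgeCount}: number of nonzero off-diagonal entries.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname accessors
#' @export
setMethod("edgeCount", "SignedNetwork", function(x) {
    w <- x@weights
    sum(w != 0 & row(w) != col(w))
})

#' @rdname accessors
#' @export
setMethod("edgeCount", "CombinedNetwork", function(x) {
    nrow(x@regulatoryEdges) + nrow(x@interactionEdges)
})

#' @rdname accessors
#' @return \code{nodeCount}: number of nodes.
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname accessors
#' @export
setMethod("nodeCount", "SignedNetwork", function(x) length(x@nodeIds))

#' @rdname accessors
#' @export
setMethod("nodeCount", "CombinedNetwork", function(x) {
    length(x@genes) + length(x@proteins)
})

#' @rdname accessors
#' @return \code{pvalueMatrix}: per-edge p-values (NA off the edge set).
#' @export
setGeneric("pvalueMatrix", function(x) standardGeneric("pvalueMatrix"))

#' @rdname accessors
#' @export
setMethod("pvalueMatrix", "InferredNetwork", function(x) x@pvalues)

#' Edge list of a network
#'
#' Flattens a network into a data.frame with one row per directed edge
#' (\code{regulator}, \code{target}, \code{weight}, and for inferred
#' networks \code{p_value} and \code{sign}), in canonical lexicographic
#' order (regulator, then target) so that serializations are byte-stable.
#'
#' @param x a [SignedNetwork-class] or [InferredNetwork-class].
#' @return data.frame of edges.
#' @examples
#' net <- signedNetwork(matrix(c(-1, 2, 0, -1), 2), c("a", "b"))
#' edgeList(net)
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname edgeList
#' @export
setMethod("edgeList", "SignedNetwork", function(x) {
    w <- x@weights
    idx <- which(w != 0 & row(w) != col(w), arr.ind = TRUE)
    df <- data.frame(
        regulator = x@nodeIds[idx[, "col"]],
        target = x@nodeIds[idx[, "row"]],
        weight = w[idx],
        stringsAsFactors = FALSE)
    df[order(df$regulator, df$target, method = "radix"), , drop = FALSE] |>
        `rownames<-`(NULL)
})

#' @rdname edgeList
#' @export
setMethod("edgeList", "InferredNetwork", function(x) {
    w <- x@weights
    idx <- which(w != 0 & row(w) != col(w), arr.ind = TRUE)
    df <- data.frame(
        regulator = x@nodeIds[idx[, "col"]],
        target = x@nodeIds[idx[, "row"]],
        weight = w[idx],
        p_value = x@pvalues[idx],
        sign = as.integer(sign(w[idx])),
        stringsAsFactors = FALSE)
    df[order(df$regulator, df$target, method = "radix"), , drop = FALSE] |>
        `rownames<-`(NULL)
})

#' Expression / perturbation value accessors
#'
#' @param x an [ExpressionDataset-class] or [PerturbationMatrix-class].
#' @return numeric matrix of values.
#' @export
exprValues <- function(x) {
    stopifnot(is(x, "ExpressionDataset"))
    assay(x, "exprs")
}

#' @rdname exprValues
#' @export
perturbValues <- function(x) {
    stopifnot(is(x, "PerturbationMatrix"))
    assay(x, "perturb")
}

setMethod("show", "SignedNetwork", function(object) {
    cat(sprintf("%s with %d nodes and %d edges\n", class(object),
                nodeCount(object), edgeCount(object)))
    ids <- object@nodeIds
    cat("  nodes: ", paste(utils::head(ids, 6), collapse = ", "),
        if (length(ids) > 6) ", ..." else "", "\n", sep = "")
})

setMethod("show", "InferredNetwork", function(object) {
    callNextMethod()
    el <- edgeList(object)
    if (nrow(el))
        cat(sprintf("  edge p-values: min %.3g, median %.3g\n",
                    min(el$p_value), stats::median(el$p_value)))
    if (length(object@metadata$failedGenes))
        cat("  failed genes:",
            paste(object@metadata$failedGenes, collapse = ", "), "\n")
})

setMethod("show", "SelectedModel", function(object) {
    cat(sprintf("SelectedModel for '%s': %d regulator(s), RSS = %.4g\n",
                object@target, length(object@regulators), object@rss))
    if (length(object@regulators)) {
        df <- data.frame(regulator = object@regulators,
                         coefficient = object@coefficients,
                         p_value = object@pvalues)
        print(df, row.names = FALSE)
    }
})

setMethod("show", "EvaluationMetrics", function(object) {
    cat("EvaluationMetrics (directed unsigned edges)\n")
    cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n",
                object@tp, object@fp, object@fn, object@tn))
    cat(sprintf("  sensitivity %.3f  precision %.3f  specificity %.3f  F1 %.3f\n",
                object@sensitivity, object@precision, object@specificity,
                object@f1))
    cat(sprintf("  sign accuracy on TP edges: %.3f\n", object@signAccuracy))
})

setMethod("show", "CombinedNetwork", function(object) {
    cat(sprintf(
        "CombinedNetwork: %d nodes (%d genes + %d proteins), %d edges (%d regulatory + %d interaction)\n",
        nodeCount(object), length(object@genes), length(object@proteins),
        edgeCount(object), nrow(object@regulatoryEdges),
        nrow(object@interactionEdges)))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d nodes, %d edges, %.0f%% negative, noise sd %g, self-decay %g, mode %s, seed %d\n",
        object@nNodes, object@nEdges, 100 * object@fractionNegative,
        object@noiseSd, object@selfDecay, object@mode, object@seed))
})

setMethod("show", "SwniConfig", function(object) {
    cat(sprintf(
        "SwniConfig: enter %g / remove %g / edge %g, maxRegulators %s, self-edges %s, mode %s\n",
        object@alphaEnter, object@alphaRemove, object@alphaEdge,
        ifelse(is.na(object@maxRegulators), "auto",
               as.character(object@maxRegulators)),
        ifelse(object@allowSelfEdges, "allowed", "excluded"), object@mode))
})
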