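#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

#' SignedNetwork: a directed, signed gene regulatory network
#'
#' Houses the regulatory coefficient matrix \eqn{A = (a_{ij})} of a linear
#' expression model: entry \code{weights[i, j]} is the effect of gene \eqn{j}
#' on gene \eqn{i} (expression change per expression unit per time unit), so
#' the edge set is \eqn{\{j \to i : a_{ij} \neq 0\}} over the off-diagonal.
#' Networks produced by the simulator carry a strictly negative diagonal
#' (self-degradation), which keeps the system stable and invertible; inferred
#' networks have a zero diagonal because self-edges are not reported.
#'
#' @slot nodeIds character vector of unique gene identifiers, one per row.
#' @slot weights square numeric matrix, dimnames equal to \code{nodeIds}.
#'
#' @seealso [signedNetwork()], [edgeList()], [generateScaleFreeNetwork()]
#' @export
setClass("SignedNetwork",
    representation(nodeIds = "character", weights = "matrix"))

setValidity("SignedNetwork", function(object) {
    msg <- character(0)
    w <- object@weights
    n <- length(object@nodeIds)
    if (nrow(w) != ncol(w))
        msg <- c(msg, "weight matrix must be square")
    if (nrow(w) != n)
        msg <- c(msg, "weight matrix dimension must equal number of node ids")
    if (anyDuplicated(object@nodeIds))
        msg <- c(msg, "node ids must be unique")
    if (n > 0 && (!identical(rownames(w), object@nodeIds) ||
                  !identical(colnames(w), object@nodeIds)))
        msg <- c(msg, "weight matrix dimnames must equal nodeIds")
    if (any(!is.finite(w)))
        msg <- c(msg, "weights must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct a SignedNetwork
#'
#' @param weights square numeric matrix of regulatory coefficients,
#'   \code{weights[i, j]} = effect of gene j on gene i.
#' @param nodeIds gene identifiers; defaults to \code{rownames(weights)} or
#'   \code{g1..gn}.
#' @return A [SignedNetwork-class] object.
#' @examples
#' A <- diag(-1, 2)
#' net <- signedNetwork(A, c("geneA", "geneB"))
#' edgeCount(net)
#' @export
signedNetwork <- function(weights, nodeIds = rownames(weights)) {
    weights <- as.matrix(weights)
    if (is.null(nodeIds))
        nodeIds <- paste0("g", seq_len(nrow(weights)))
    nodeIds <- as.character(nodeIds)
    dimnames(weights) <- list(nodeIds, nodeIds)
    new("SignedNetwork", nodeIds = nodeIds, weights = weights)
}

#' InferredNetwork: a SignedNetwork with per-edge significance
#'
#' The result of stepwise network inference: estimated coefficients
#' \eqn{\hat a_{ij}} together with the two-sided p-value of each retained
#' coefficient. Entries without an edge are 0 in \code{weights} and \code{NA}
#' in \code{pvalues}. Per-run bookkeeping (configuration echo, failed genes,
#' dropped zero-variance predictors) lives in \code{metadata}.
#'
#' @slot pvalues numeric matrix aligned with \code{weights}; p in (0, 1] on
#'   edges, NA elsewhere.
#' @slot metadata list of run information.
#' @seealso [inferNetwork()], [tightenNetwork()], [evaluateNetwork()]
#' @export
setClass("InferredNetwork", contains = "SignedNetwork",
    representation(pvalues = "matrix", metadata = "list"))

setValidity("InferredNetwork", function(object) {
    msg <- character(0)
    if (!identical(dim(object@pvalues), dim(object@weights)))
        msg <- c(msg, "pvalues must be aligned with weights")
    edge <- object@weights != 0 & row(object@weights) != col(object@weights)
    p <- object@pvalues[edge]
    if (length(p) && (any(is.na(p)) || any(p <= 0) || any(p > 1)))
        msg <- c(msg, "every edge must carry a p-value in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct an InferredNetwork
#'
#' @param weights,nodeIds as in [signedNetwork()].
#' @param pvalues numeric matrix of per-edge p-values aligned with
#'   \code{weights} (NA off the edge set).
#' @param metadata list of run information.
#' @return An [InferredNetwork-class] object.
#' @export
inferredNetwork <- function(weights, pvalues, nodeIds = rownames(weights),
                            metadata = list()) {
    base <- signedNetwork(weights, nodeIds)
    pvalues <- as.matrix(pvalues)
    dimnames(pvalues) <- dimnames(base@weights)
    new("InferredNetwork", base, pvalues = pvalues, metadata = metadata)
}

#' ExpressionDataset: gene-by-experiment expression values
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' holding the expression matrix \eqn{X} (n genes by m experiments) in assay
#' \code{"exprs"}, with per-experiment labels and optional time values in
#' \code{colData}.
#'
#' @seealso [expressionDataset()], [exprValues()], [simulateSteadyState()]
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character(0)
    if (!"exprs" %in% names(assays(object)))
        msg <- c(msg, "assay 'exprs' is required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "unique gene ids (rownames) are required")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, genes in rows, experiments in columns.
#' @param geneIds row identifiers; defaults to rownames.
#' @param labels experiment labels; defaults to colnames or \code{e1..em}.
#' @param time optional numeric vector of timepoints per experiment.
#' @return An [ExpressionDataset-class] object.
#' @examples
#' x <- expressionDataset(matrix(rnorm(6), 2), geneIds = c("a", "b"))
#' dim(exprValues(x))
#' @export
expressionDataset <- function(values, geneIds = rownames(values),
                              labels = colnames(values), time = NULL) {
    values <- as.matrix(values)
    if (is.null(geneIds)) geneIds <- paste0("g", seq_len(nrow(values)))
    if (is.null(labels)) labels <- paste0("e", seq_len(ncol(values)))
    dimnames(values) <- list(as.character(geneIds), as.character(labels))
    cd <- DataFrame(label = as.character(labels), row.names = labels)
    if (!is.null(time)) {
        stopifnot(length(time) == ncol(values))
        cd$time <- as.numeric(time)
    }
    se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
    new("ExpressionDataset", se)
}

#' PerturbationMatrix: external stimuli per gene per experiment
#'
#' Holds the stimulus matrix \eqn{P = (p_{ij})}: \code{p[i, j]} is the
#' external perturbation applied to gene \eqn{i} in experiment \eqn{j}
#' (e.g. a sustained knockout is encoded as \eqn{-1}). Shape and identifiers
#' must match the paired [ExpressionDataset-class]; all-zero columns are
#' unperturbed controls.
#'
#' @seealso [perturbationMatrix()], [knockoutDesign()]
#' @export
setClass("PerturbationMatrix", contains = "SummarizedExperiment")

setValidity("PerturbationMatrix", function(object) {
    msg <- character(0)
    if (!"perturb" %in% names(assays(object)))
        msg <- c(msg, "assay 'perturb' is required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "unique gene ids (rownames) are required")
    if (length(msg)) msg else TRUE
})

#' Construct a PerturbationMatrix
#'
#' @param values numeric matrix of stimuli, genes in rows.
#' @param geneIds,labels as in [expressionDataset()].
#' @return A [PerturbationMatrix-class] object.
#' @export
perturbationMatrix <- function(values, geneIds = rownames(values),
                               labels = colnames(values)) {
    values <- as.matrix(values)
    if (is.null(geneIds)) geneIds <- paste0("g", seq_len(nrow(values)))
    if (is.null(labels)) labels <- paste0("e", seq_len(ncol(values)))
    dimnames(values) <- list(as.character(geneIds), as.character(labels))
    cd <- DataFrame(label = as.character(labels), row.names = labels)
    se <- SummarizedExperiment(assays = list(perturb = values), colData = cd)
    new("PerturbationMatrix", se)
}

#' SelectedModel: stepwise-regression result for one target gene
#'
#' @slot target target gene identifier.
#' @slot regulators selected regulator ids, in order of final model.
#' @slot coefficients estimated \eqn{\hat a_{ij}} on the original scale.
#' @slot pvalues two-sided p-value per retained coefficient.
#' @slot rss residual sum of squares of the final model.
#' @slot steps data.frame log of the selection path
#'   (action, variable, pvalue).
#' @seealso [forwardStepwise()]
#' @export
setClass("SelectedModel",
    representation(target = "character", regulators = "character",
                   coefficients = "numeric", pvalues = "numeric",
                   rss = "numeric", steps = "data.frame"))

setValidity("SelectedModel", function(object) {
    msg <- character(0)
    k <- length(object@regulators)
    if (length(object@coefficients) != k || length(object@pvalues) != k)
        msg <- c(msg, "coefficients and pvalues must match regulators")
    if (length(msg)) msg else TRUE
})

#' EvaluationMetrics: directed-edge confusion summary vs ground truth
#'
#' Counts are over directed unsigned edges (self-edges excluded when
#' disallowed); rates with a zero denominator are reported as \code{NA}
#' (undefined), never as 0. Sign accuracy is computed over true-positive
#' edges only.
#'
#' @slot tp,fp,fn,tn integer confusion counts.
#' @slot sensitivity,specificity,precision,f1,signAccuracy numeric rates.
#' @seealso [evaluateNetwork()]
#' @export
setClass("EvaluationMetrics",
    representation(tp = "integer", fp = "integer", fn = "integer",
                   tn = "integer", sensitivity = "numeric",
                   specificity = "numeric", precision = "numeric",
                   f1 = "numeric", signAccuracy = "numeric"))

#' CombinedNetwork: gene regulations merged with protein interactions
#'
#' A two-layer network: typed nodes (gene or protein), directed regulatory
#' edges between gene nodes, and undirected interaction edges between protein
#' nodes, each edge tagged with its provenance. Gene and protein identifier
#' spaces must be disjoint.
#'
#' @slot genes,proteins node identifiers per type.
#' @slot regulatoryEdges data.frame (from, to, weight, provenance).
#' @slot interactionEdges data.frame (a, b, provenance), canonically ordered
#'   so that a <= b; duplicates collapsed.
#' @slot metadata list (e.g. collapsed duplicate counts).
#' @seealso [mergePpi()]
#' @export
setClass("CombinedNetwork",
    representation(genes = "character", proteins = "character",
                   regulatoryEdges = "data.frame",
                   interactionEdges = "data.frame", metadata = "list"))

setValidity("CombinedNetwork", function(object) {
    msg <- character(0)
    if (length(intersect(object@genes, object@proteins)))
        msg <- c(msg, "gene and protein identifier spaces must be disjoint")
    re <- object@regulatoryEdges
    ie <- object@interactionEdges
    if (nrow(re) && !all(c(re$from, re$to) %in% object@genes))
        msg <- c(msg, "regulatory edges must connect gene nodes")
    if (nrow(ie) && !all(c(ie$a, ie$b) %in% object@proteins))
        msg <- c(msg, "interaction edges must connect protein nodes")
    if (nrow(re) && anyDuplicated(re[, c("from", "to")]))
        msg <- c(msg, "duplicate regulatory edges")
    if (nrow(ie) && anyDuplicated(ie[, c("a", "b")]))
        msg <- c(msg, "duplicate interaction edges")
    if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Bundles the parameters of the scale-free generator and expression
#' simulator. Defaults encode a sparse signed network with uniform edge
#' magnitudes in (0.5, 1.5), half the edges repressive, and a self-decay of
#' -2 per gene which keeps the coefficient matrix comfortably invertible.
#'
#' @param nNodes number of genes.
#' @param nEdges number of off-diagonal (cross-regulation) edges; must not
#'   exceed \code{nNodes * (nNodes - 1)}.
#' @param fractionNegative probability an edge is repressive (negative).
#' @param noiseSd standard deviation of additive Gaussian measurement noise.
#' @param seed integer seed; fully determines generator output.
#' @param mode \code{"steady_state"} (default; snapshots with \eqn{\dot X = 0})
#'   or \code{"time_series"} (explicit Euler trajectories).
#' @param selfDecay strictly negative diagonal entry (self-degradation rate).
#' @return A \code{SimulationConfig} object.
#' @examples
#' cfg <- simulationConfig(nNodes = 10, nEdges = 15, seed = 1)
#' @export
simulationConfig <- function(nNodes, nEdges, fractionNegative = 0.5,
                             noiseSd = 0, seed = 1L,
                             mode = c("steady_state", "time_series"),
                             selfDecay = -2) {
    mode <- match.arg(mode)
    new("SimulationConfig", nNodes = as.integer(nNodes),
        nEdges = as.integer(nEdges),
        fractionNegative = as.numeric(fractionNegative),
        noiseSd = as.numeric(noiseSd), seed = as.integer(seed),
        mode = mode, selfDecay = as.numeric(selfDecay))
}

#' @rdname simulationConfig
#' @export
setClass("SimulationConfig",
    representation(nNodes = "integer", nEdges = "integer",
                   fractionNegative = "numeric", noiseSd = "numeric",
                   seed = "integer", mode = "character",
                   selfDecay = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    n <- object@nNodes
    if (n < 1) msg <- c(msg, "nNodes must be positive")
    if (object@nEdges < 0) msg <- c(msg, "nEdges must be nonnegative")
    if (object@nEdges > n * (n - 1))
        msg <- c(msg, sprintf(
            "infeasible edge count: %d edges requested but at most %d directed edges fit on %d nodes",
            object@nEdges, n * (n - 1L), n))
    if (n < 2 && object@nEdges > 0)
        msg <- c(msg, "at least 2 nodes are required for any edge")
    if (object@fractionNegative < 0 || object@fractionNegative > 1)
        msg <- c(msg, "fractionNegative must lie in [0, 1]")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
    if (!object@mode %in% c("steady_state", "time_series"))
        msg <- c(msg, "mode must be steady_state or time_series")
    if (object@selfDecay >= 0) msg <- c(msg, "selfDecay must be negative")
    if (length(msg)) msg else TRUE
})

#' Stepwise-inference configuration
#'
#' Significance thresholds and limits for per-gene stepwise regulator
#' selection. Entry and removal both default to the conventional 5% level:
#' a stricter entry gate makes greedy selection stall behind proxy
#' regulators (a marginally significant correlate blocks the true regulators
#' whose individual partial F-tests are diluted by each other), while the
#' backward-removal phase cleans up proxies once the true set is in. False
#' edges are instead controlled by the stricter final edge test
#' \code{alphaEdge} (default 1%) on the fitted model's coefficients; see the
#' methods vignette for the calibration.
#'
#' @param alphaEnter partial-F p-value below which a candidate enters
#'   (\code{alphaEnter <= alphaRemove}).
#' @param alphaRemove p-value at or above which an included variable is
#'   removed.
#' @param alphaEdge final edge-retention significance level applied to the
#'   selected model's coefficient p-values.
#' @param maxRegulators cap on selected regulators per gene; \code{NA} means
#'   choose \code{min(10, m - 2)} at run time from the number of
#'   experiments m.
#' @param allowSelfEdges whether a gene may be its own candidate regulator.
#' @param mode \code{"steady_state"} or \code{"time_series"} (finite
#'   difference derivatives).
#' @return A \code{SwniConfig} object.
#' @examples
#' cfg <- swniConfig(alphaEnter = 0.01, alphaRemove = 0.05)
#' @export
swniConfig <- function(alphaEnter = 0.05, alphaRemove = 0.05,
                       alphaEdge = 0.01, maxRegulators = NA_integer_,
                       allowSelfEdges = FALSE,
                       mode = c("steady_state", "time_series")) {
    mode <- match.arg(mode)
    new("SwniConfig", alphaEnter = as.numeric(alphaEnter),
        alphaRemove = as.numeric(alphaRemove),
        alphaEdge = as.numeric(alphaEdge),
        maxRegulators = as.integer(maxRegulators),
        allowSelfEdges = isTRUE(allowSelfEdges), mode = mode)
}

#' @rdname swniConfig
#' @export
setClass("SwniConfig",
    representation(alphaEnter = "numeric", alphaRemove = "numeric",
                   alphaEdge = "numeric", maxRegulators = "integer",
                   allowSelfEdges = "logical", mode = "character"))

setValidity("SwniConfig", function(object) {
    msg <- character(0)
    for (nm in c("alphaEnter", "alphaRemove", "alphaEdge")) {
        a <- slot(object, nm)
        if (!(a > 0 && a <= 1)) msg <- c(msg, paste(nm, "must lie in (0, 1]"))
    }
    if (object@alphaEnter > object@alphaRemove)
        msg <- c(msg, "alphaEnter must not exceed alphaRemove")
    if (!is.na(object@maxRegulators) && object@maxRegulators < 1)
        msg <- c(msg, "maxRegulators must be positive")
    if (length(msg)) msg else TRUE
})
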