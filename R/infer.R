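#' Build per-gene regression problems from a perturbation compendium
#'
#' Under the steady-state model \eqn{A X = -P}, row i of A satisfies
#' \eqn{\sum_j a_{ij} x_j = -p_i} in every experiment, so gene i's regression
#' problem has response \eqn{(-p_{i1}, \dots, -p_{im})} and the transposed
#' expression matrix (experiments x genes) as candidate predictors. In
#' time-series mode the response is the finite-difference derivative
#' \eqn{\dot x_i} minus \eqn{p_i} (central differences in the interior,
#' forward/backward at the ends) and at least 3 timepoints are required.
#' The target gene is excluded from its own candidates unless
#' \code{config@allowSelfEdges}; its own expression is instead supplied as a
#' forced covariate (always in the model, never reported), which absorbs the
#' self-decay term \eqn{a_{ii} x_i} — without it every per-gene regression
#' would be misspecified. Zero-variance candidate columns are dropped and
#' reported.
#'
#' @param X an [ExpressionDataset-class].
#' @param P a [PerturbationMatrix-class] aligned with \code{X}.
#' @param config a [swniConfig()].
#' @return named list, one element per gene:
#'   \code{list(target, response, candidates, droppedCandidates)}.
#' @export
buildRegressionProblems <- function(X, P, config = swniConfig()) {
    stopifnot(is(X, "ExpressionDataset"), is(P, "PerturbationMatrix"))
    xv <- exprValues(X)
    pv <- perturbValues(P)
    if (!identical(dim(xv), dim(pv)) || !identical(rownames(xv), rownames(pv)))
        stop(sprintf(
            "expression (%d x %d) and perturbation (%d x %d) matrices are misaligned",
            nrow(xv), ncol(xv), nrow(pv), ncol(pv)))
    genes <- rownames(xv)
    m <- ncol(xv)
    if (config@mode == "time_series") {
        if (m < 3)
            stop("time-series mode requires at least 3 timepoints")
        time <- colData(X)$time
        if (is.null(time)) time <- seq_len(m)
        # finite-difference derivative per gene: central in the interior,
        # one-sided at the ends
        deriv <- t(apply(xv, 1, function(x) {
            d <- numeric(m)
            d[1] <- (x[2] - x[1]) / (time[2] - time[1])
            d[m] <- (x[m] - x[m - 1]) / (time[m] - time[m - 1])
            if (m > 2) {
                k <- 2:(m - 1)
                d[k] <- (x[k + 1] - x[k - 1]) / (time[k + 1] - time[k - 1])
            }
            d
        }))
    }
    predAll <- t(xv)  # experiments x genes
    sds <- apply(predAll, 2, stats::sd)
    lapply(stats::setNames(genes, genes), function(g) {
        cand <- if (config@allowSelfEdges) genes else setdiff(genes, g)
        ok <- cand[sds[cand] > 0 & is.finite(sds[cand])]
        resp <- if (config@mode == "steady_state") -pv[g, ]
                else deriv[g, ] - pv[g, ]
        forced <- if (!config@allowSelfEdges && sds[g] > 0 &&
                      is.finite(sds[g]))
            predAll[, g, drop = FALSE] else NULL
        list(target = g, response = as.numeric(resp),
             candidates = predAll[, ok, drop = FALSE],
             forced = forced,
             droppedCandidates = setdiff(cand, ok))
    })
}

#' Infer a gene regulatory network by per-gene stepwise regression
#'
#' Runs [forwardStepwise()] on every gene's regression problem (see
#' [buildRegressionProblems()]) and assembles the selected regulators into a
#' directed, signed [InferredNetwork-class]: an edge j -> i for every
#' retained regulator j of gene i, weighted by the estimated coefficient
#' \eqn{\hat a_{ij}} with its p-value attached. Edges whose p-value is at or
#' above \code{config@alphaEdge} are dropped. A failure in one gene's
#' problem is recorded and does not abort the run.
#'
#' @param X an [ExpressionDataset-class] (n genes x m experiments).
#' @param P a [PerturbationMatrix-class] aligned with \code{X}.
#' @param config a [swniConfig()].
#' @param returnModels keep the per-gene [SelectedModel-class]s in the
#'   result metadata.
#' @return An [InferredNetwork-class]. \code{metadata} carries the config,
#'   per-gene failures, and dropped zero-variance candidates.
#' @examples
#' sim <- simulateBenchmark(simulationConfig(10, 15, seed = 3))
#' net <- inferNetwork(sim$expression, sim$design)
#' edgeCount(net)
#' @export
inferNetwork <- function(X, P, config = swniConfig(), returnModels = FALSE) {
    problems <- buildRegressionProblems(X, P, config)
    genes <- names(problems)
    models <- lapply(problems, function(pr)
        tryCatch(forwardStepwise(pr$response, pr$candidates, config,
                                 target = pr$target, forced = pr$forced),
                 error = function(e) e))
    .assembleNetwork(models, genes, config, returnModels)
}

.assembleNetwork <- function(models, genes, config, returnModels = FALSE) {
    n <- length(genes)
    w <- matrix(0, n, n, dimnames = list(genes, genes))
    pm <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
    failed <- character(0)
    for (g in genes) {
        fit <- models[[g]]
        if (inherits(fit, "error")) {
            failed <- c(failed, g)
            next
        }
        keep <- fit@pvalues < config@alphaEdge
        regs <- fit@regulators[keep]
        w[g, regs] <- fit@coefficients[keep]
        pm[g, regs] <- fit@pvalues[keep]
    }
    meta <- list(config = config, failedGenes = failed)
    if (returnModels)
        meta$models <- models
    inferredNetwork(w, pm, genes, metadata = meta)
}

#' Tighten an inferred network by raising the significance level
#'
#' Keeps exactly the edges with p-value strictly below \code{alpha} and
#' drops nodes left with no incident edge, mirroring the extraction of a
#' sparser, higher-confidence network from a first-pass one. Nested by
#' construction: lowering \code{alpha} can only shrink the edge set.
#'
#' @param net an [InferredNetwork-class].
#' @param alpha retention level in (0, 1].
#' @param dropIsolated drop nodes with no incident edges (default TRUE).
#' @return An [InferredNetwork-class] restricted to the surviving edges.
#' @examples
#' sim <- simulateBenchmark(simulationConfig(10, 15, seed = 3))
#' net <- inferNetwork(sim$expression, sim$design)
#' edgeCount(tightenNetwork(net, 1e-6)) <= edgeCount(net)
#' @export
tightenNetwork <- function(net, alpha, dropIsolated = TRUE) {
    stopifnot(is(net, "InferredNetwork"), alpha > 0, alpha <= 1)
    w <- net@weights
    p <- net@pvalues
    kill <- !is.na(p) & p >= alpha
    w[kill] <- 0
    p[w == 0] <- NA_real_
    if (dropIsolated) {
        edge <- w != 0 & row(w) != col(w)
        live <- rowSums(edge) > 0 | colSums(edge) > 0
        if (!any(live)) live[] <- FALSE
        w <- w[live, live, drop = FALSE]
        p <- p[live, live, drop = FALSE]
        ids <- net@nodeIds[live]
    } else {
        ids <- net@nodeIds
    }
    inferredNetwork(w, p, ids, metadata = net@metadata)
}

#' Evaluate an inferred network against ground truth
#'
#' Confusion counts over directed unsigned edges on the shared node
#' universe. Self-pairs are excluded when \code{excludeSelf} (the default,
#' matching inference without self-edges), so the four counts sum to
#' \eqn{n(n-1)}. Rates with zero denominator are \code{NA} (undefined), not
#' 0. Sign accuracy compares the sign of the estimated and true coefficient
#' over true-positive edges only.
#'
#' @param inferred an [InferredNetwork-class] (or [SignedNetwork-class]).
#' @param truth a [SignedNetwork-class] on the same node set.
#' @param excludeSelf exclude the diagonal from the comparison.
#' @return An [EvaluationMetrics-class].
#' @examples
#' truth <- signedNetwork(matrix(c(-1, 1, 0, -1), 2), c("a", "b"))
#' evaluateNetwork(truth, truth)@sensitivity  # 1
#' @export
evaluateNetwork <- function(inferred, truth, excludeSelf = TRUE) {
    stopifnot(is(inferred, "SignedNetwork"), is(truth, "SignedNetwork"))
    if (!setequal(nodeIds(inferred), nodeIds(truth))) {
        diffs <- c(setdiff(nodeIds(inferred), nodeIds(truth)),
                   setdiff(nodeIds(truth), nodeIds(inferred)))
        stop("node sets differ; symmetric difference: ",
             paste(diffs, collapse = ", "))
    }
    ids <- nodeIds(truth)
    wi <- weightMatrix(inferred)[ids, ids]
    wt <- weightMatrix(truth)[ids, ids]
    off <- if (excludeSelf) row(wt) != col(wt) else matrix(TRUE, nrow(wt), ncol(wt))
    predicted <- (wi != 0) & off
    actual <- (wt != 0) & off
    tp <- sum(predicted & actual)
    fp <- sum(predicted & !actual)
    fn <- sum(!predicted & actual)
    tn <- sum(!predicted & !actual & off)
    rate <- function(num, den) if (den > 0) num / den else NA_real_
    sens <- rate(tp, tp + fn)
    prec <- rate(tp, tp + fp)
    spec <- rate(tn, tn + fp)
    f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
        2 * sens * prec / (sens + prec) else NA_real_
    signAcc <- if (tp > 0) {
        hits <- predicted & actual
        mean(sign(wi[hits]) == sign(wt[hits]))
    } else NA_real_
    new("EvaluationMetrics", tp = as.integer(tp), fp = as.integer(fp),
        fn = as.integer(fn), tn = as.integer(tn), sensitivity = sens,
        specificity = spec, precision = prec, f1 = f1, signAccuracy = signAcc)
}
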