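#' Generate an artificial scale-free signed regulatory network
#'
#' Grows a directed network by preferential attachment: nodes arrive one at
#' a time and connect to existing nodes with probability proportional to
#' (total degree + 1); each new edge is oriented uniformly at random. A final
#' adjustment phase adds or removes uniformly random edges so the off-diagonal
#' edge count equals \code{nEdges} exactly. The resulting total-degree
#' distribution is heavy-tailed (approximately power-law). Nonzero
#' off-diagonal magnitudes are drawn Uniform(0.5, 1.5) with sign negative
#' with probability \code{fractionNegative}; every diagonal entry is the
#' strictly negative \code{selfDecay}, modelling first-order
#' self-degradation and keeping the coefficient matrix invertible.
#'
#' @param config a [simulationConfig()] object.
#' @return A [SignedNetwork-class] with exactly \code{config@nEdges} edges.
#' @examples
#' net <- generateScaleFreeNetwork(simulationConfig(50, 120, seed = 7))
#' edgeCount(net)  # 120
#' @export
generateScaleFreeNetwork <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    n <- config@nNodes
    target <- config@nEdges
    if (n >= 2 && target / (n * (n - 1)) > 0.5)
        warning(sprintf(
            "requested density %.2f exceeds 0.5; such a dense network cannot be scale-free",
            target / (n * (n - 1))))
    set.seed(config@seed)
    adj <- matrix(FALSE, n, n)  # adj[i, j]: edge j -> i
    deg <- integer(n)
    if (n >= 2 && target > 0) {
        # per-arrival edge budget summing exactly to `target`
        quota <- diff(floor(cumsum(rep(target / (n - 1), n - 1)) + 1e-9))
        quota <- c(floor(target / (n - 1) + 1e-9), quota)
        for (v in seq(2, n)) {
            k <- min(quota[v - 1], v - 1L)
            for (e in seq_len(k)) {
                u <- sample.int(v - 1L, 1L, prob = deg[seq_len(v - 1)] + 1)
                if (stats::runif(1) < 0.5) { from <- u; to <- v }
                else { from <- v; to <- u }
                if (!adj[to, from]) {
                    adj[to, from] <- TRUE
                    deg[from] <- deg[from] + 1L
                    deg[to] <- deg[to] + 1L
                }
            }
        }
        # adjust to the exact requested count with uniformly random edges
        count <- sum(adj)
        if (count < target) {
            free <- which(!adj & row(adj) != col(adj))
            adj[free[sample.int(length(free), target - count)]] <- TRUE
        } else if (count > target) {
            cur <- which(adj)
            adj[cur[sample.int(length(cur), count - target)]] <- FALSE
        }
    }
    nEdge <- sum(adj)
    w <- matrix(0, n, n)
    if (nEdge > 0) {
        mag <- stats::runif(nEdge, 0.5, 1.5)
        sgn <- ifelse(stats::runif(nEdge) < config@fractionNegative, -1, 1)
        w[which(adj)] <- mag * sgn
    }
    diag(w) <- config@selfDecay
    signedNetwork(w, paste0("g", seq_len(n)))
}

#' Knockout perturbation design
#'
#' Builds the stimulus matrix P for a series of single-gene perturbation
#' experiments: experiment j applies a sustained stimulus of \code{value}
#' (default -1, a knockout) to gene \code{targets[j]} and nothing else.
#'
#' @param geneIds all gene identifiers (rows of P).
#' @param targets perturbed gene per experiment; defaults to one knockout per
#'   gene. Repeats are allowed (replicate perturbations).
#' @param value stimulus applied to the perturbed gene.
#' @param labels experiment labels.
#' @return A [PerturbationMatrix-class].
#' @examples
#' P <- knockoutDesign(c("a", "b", "c"))
#' perturbValues(P)
#' @export
knockoutDesign <- function(geneIds, targets = geneIds, value = -1,
                           labels = NULL) {
    stopifnot(all(targets %in% geneIds))
    p <- matrix(0, length(geneIds), length(targets))
    p[cbind(match(targets, geneIds), seq_along(targets))] <- value
    if (is.null(labels))
        labels <- make.unique(paste0("ko_", targets), sep = "_r")
    perturbationMatrix(p, geneIds = geneIds, labels = labels)
}

#' Simulate steady-state perturbation expression data
#'
#' Under the linear model \eqn{\dot X = A X + P}, a sustained perturbation
#' snapshot is taken at steady state (\eqn{\dot X = 0}), so each experiment
#' column solves \eqn{A x = -p}. Optional i.i.d. Gaussian measurement noise
#' is added elementwise.
#'
#' @param network a [SignedNetwork-class] (A must be well-conditioned).
#' @param design a [PerturbationMatrix-class] with matching gene ids.
#' @param noiseSd standard deviation of additive Gaussian noise (0 = exact).
#' @param seed integer seed for the noise draw; required when noiseSd > 0.
#' @return An [ExpressionDataset-class] with one column per experiment.
#' @examples
#' net <- signedNetwork(diag(-1, 2), c("a", "b"))
#' P <- knockoutDesign(c("a", "b"))
#' exprValues(simulateSteadyState(net, P))
#' @export
simulateSteadyState <- function(network, design, noiseSd = 0, seed = 1L) {
    stopifnot(is(network, "SignedNetwork"), is(design, "PerturbationMatrix"))
    if (!identical(nodeIds(network), rownames(design)))
        stop("network and design gene ids differ")
    A <- weightMatrix(network)
    rc <- rcond(A)
    if (!is.finite(rc) || rc < 1e-12)
        stop(sprintf(
            "coefficient matrix is numerically singular (reciprocal condition estimate %.3g)",
            rc))
    P <- perturbValues(design)
    X <- solve(A, -P)
    if (noiseSd > 0) {
        set.seed(seed)
        X <- X + matrix(stats::rnorm(length(X), sd = noiseSd),
                        nrow(X), ncol(X))
    }
    expressionDataset(X, geneIds = nodeIds(network),
                      labels = colnames(design))
}

#' Simulate an expression time course by explicit Euler integration
#'
#' Integrates \eqn{\dot x = A x + p} from \code{x0} with fixed step
#' \code{dt}: \eqn{x_{t+1} = x_t + dt (A x_t + p)}. The trajectory (including
#' the initial state at t = 0) is returned column-by-column with timepoints
#' recorded in the experiment metadata.
#'
#' @param network a [SignedNetwork-class].
#' @param x0 initial expression vector (length = number of genes).
#' @param p constant stimulus vector (one perturbation-design column).
#' @param dt positive step size (time units).
#' @param nSteps number of Euler steps (>= 1).
#' @param noiseSd sd of Gaussian measurement noise added to the recorded
#'   trajectory (the dynamics stay deterministic).
#' @param seed seed for the noise draw.
#' @return An [ExpressionDataset-class] with \code{nSteps + 1} columns and
#'   \code{colData(x)$time} giving the timepoints.
#' @examples
#' net <- signedNetwork(matrix(-1, 1, 1), "a")
#' x <- simulateTimeSeries(net, x0 = 0, p = 1, dt = 0.01, nSteps = 2000)
#' tail(exprValues(x)[1, ], 1)  # near the fixed point 1.0
#' @export
simulateTimeSeries <- function(network, x0, p, dt, nSteps, noiseSd = 0,
                               seed = 1L) {
    stopifnot(is(network, "SignedNetwork"), dt > 0, nSteps >= 1)
    A <- weightMatrix(network)
    n <- nrow(A)
    stopifnot(length(x0) == n, length(p) == n)
    X <- matrix(NA_real_, n, nSteps + 1)
    x <- as.numeric(x0)
    X[, 1] <- x
    for (k in seq_len(nSteps)) {
        x <- x + dt * (A %*% x + p)[, 1]
        if (any(!is.finite(x)) || max(abs(x)) > 1e8)
            stop(sprintf(
                "trajectory diverged at step %d (|x| exceeded 1e8); try a smaller dt",
                k))
        X[, k + 1] <- x
    }
    if (noiseSd > 0) {
        set.seed(seed)
        X <- X + matrix(stats::rnorm(length(X), sd = noiseSd),
                        nrow(X), ncol(X))
    }
    times <- dt * (0:nSteps)
    expressionDataset(X, geneIds = nodeIds(network),
                      labels = sprintf("t_%d", 0:nSteps), time = times)
}

#' One-call simulation of a benchmark problem
#'
#' Convenience wrapper: generates a scale-free truth network from
#' \code{config}, builds a knockout design (one experiment per entry of
#' \code{targets}), and simulates steady-state expression with the
#' configured noise.
#'
#' @param config a [simulationConfig()].
#' @param targets perturbed gene per experiment; default one knockout per
#'   gene.
#' @return list with elements \code{network} (truth), \code{design}
#'   (PerturbationMatrix) and \code{expression} (ExpressionDataset).
#' @export
simulateBenchmark <- function(config, targets = NULL) {
    net <- generateScaleFreeNetwork(config)
    if (is.null(targets)) targets <- nodeIds(net)
    design <- knockoutDesign(nodeIds(net), targets = targets)
    expr <- simulateSteadyState(net, design, noiseSd = config@noiseSd,
                                seed = config@seed + 1L)
    list(network = net, design = design, expression = expr)
}
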