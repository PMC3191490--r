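#' Contiguous balanced partition of the gene index set
#'
#' Splits \code{1..n} into \code{k} contiguous blocks whose sizes differ by
#' at most one (the first \code{n %% k} blocks get the extra gene). This is
#' the decomposition unit of the parallel engine: one block of rows of P
#' (hence rows of A) per worker.
#'
#' @param n number of genes.
#' @param k number of blocks.
#' @return list of integer index vectors.
#' @examples
#' lengths(partitionGeneBlocks(100, 8))  # 13 13 13 13 12 12 12 12
#' @export
partitionGeneBlocks <- function(n, k) {
    stopifnot(n >= 1, k >= 1)
    k <- min(k, n)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    Map(seq.int, starts, ends)
}

#' Parallel network inference with per-gene task decomposition
#'
#' Identical contract to [inferNetwork()]: the gene set is partitioned into
#' contiguous blocks balanced to within one gene, each worker (a forked
#' process) runs the sequential per-gene stepwise pipeline on its block, and
#' the merged result is edge-for-edge, value-for-value identical to the
#' single-worker run. Determinism holds for any worker count because each
#' gene's problem is self-contained and the stepwise path uses no random
#' numbers.
#'
#' @inheritParams inferNetwork
#' @param nWorkers number of workers (>= 1); clamped to the number of genes
#'   with a warning when larger.
#' @return An [InferredNetwork-class].
#' @examples
#' sim <- simulateBenchmark(simulationConfig(10, 15, seed = 3))
#' a <- inferNetwork(sim$expression, sim$design)
#' b <- inferNetworkParallel(sim$expression, sim$design, nWorkers = 2)
#' identical(edgeList(a), edgeList(b))  # TRUE
#' @export
inferNetworkParallel <- function(X, P, config = swniConfig(), nWorkers = 1L,
                                 returnModels = FALSE) {
    stopifnot(nWorkers >= 1)
    problems <- buildRegressionProblems(X, P, config)
    genes <- names(problems)
    if (nWorkers > length(genes)) {
        warning(sprintf("nWorkers (%d) exceeds number of genes (%d); clamped",
                        nWorkers, length(genes)))
        nWorkers <- length(genes)
    }
    blocks <- partitionGeneBlocks(length(genes), nWorkers)
    runBlock <- function(idx) {
        lapply(problems[idx], function(pr)
            tryCatch(forwardStepwise(pr$response, pr$candidates, config,
                                     target = pr$target, forced = pr$forced),
                     error = function(e) e))
    }
    blockResults <- if (nWorkers == 1L || .Platform$OS.type == "windows") {
        lapply(blocks, runBlock)
    } else {
        parallel::mclapply(blocks, runBlock, mc.cores = nWorkers,
                           mc.preschedule = FALSE)
    }
    for (b in seq_along(blockResults)) {
        if (inherits(blockResults[[b]], "try-error") ||
            inherits(blockResults[[b]], "error"))
            stop(sprintf("worker failed on gene block %d (genes %s..%s): %s",
                         b, genes[blocks[[b]][1]],
                         genes[utils::tail(blocks[[b]], 1)],
                         conditionMessage(attr(blockResults[[b]], "condition"))))
    }
    models <- unlist(blockResults, recursive = FALSE, use.names = FALSE)
    names(models) <- genes
    .assembleNetwork(models, genes, config, returnModels)
}

#' Benchmark wall-clock scaling over worker counts
#'
#' Runs [inferNetworkParallel()] on identical inputs for every requested
#' worker count, records the wall time, and hard-fails if any run's
#' serialized edge list differs from the 1-worker baseline (the determinism
#' contract). Absolute times are hardware-dependent and are recorded, never
#' asserted.
#'
#' @inheritParams inferNetwork
#' @param workerCounts positive integers; a baseline count of 1 is added if
#'   absent.
#' @param label problem label for the timing table.
#' @return A timing table: data.frame (worker_count, wall_time, label).
#' @seealso [speedupEfficiency()]
#' @export
benchmarkScaling <- function(X, P, config = swniConfig(),
                             workerCounts = c(1L, 2L, 4L),
                             label = "problem") {
    stopifnot(length(workerCounts) >= 1, all(workerCounts >= 1))
    workerCounts <- sort(unique(as.integer(workerCounts)))
    if (!1L %in% workerCounts) workerCounts <- c(1L, workerCounts)
    serialize <- function(net) {
        el <- edgeList(net)
        paste(el$regulator, el$target, sprintf("%.10g", el$weight),
              sprintf("%.10g", el$p_value), collapse = "\n")
    }
    baseline <- NULL
    rows <- lapply(workerCounts, function(p) {
        t0 <- proc.time()[["elapsed"]]
        net <- inferNetworkParallel(X, P, config, nWorkers = p)
        elapsed <- max(proc.time()[["elapsed"]] - t0, 1e-6)
        ser <- serialize(net)
        if (p == 1L) baseline <<- ser
        else if (!identical(ser, baseline))
            stop(sprintf(
                "parallel contract violated: %d-worker output differs from the sequential baseline",
                p))
        data.frame(worker_count = p, wall_time = elapsed, label = label,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Speedup and efficiency from a timing table
#'
#' For every worker count p, the speedup is \eqn{S_p = T_1 / T_p} and the
#' efficiency \eqn{E_p = S_p / p}; computed per problem label. The identities
#' \eqn{S_1 = 1} and \eqn{E_p = S_p / p} hold exactly.
#'
#' @param timings data.frame with columns \code{worker_count},
#'   \code{wall_time} and optionally \code{label}.
#' @return data.frame (label, worker_count, wall_time, speedup, efficiency).
#' @examples
#' speedupEfficiency(data.frame(worker_count = c(1, 4),
#'                              wall_time = c(100, 25)))
#' @export
speedupEfficiency <- function(timings) {
    stopifnot(is.data.frame(timings),
              all(c("worker_count", "wall_time") %in% names(timings)))
    if (any(timings$wall_time <= 0)) stop("wall times must be positive")
    if (is.null(timings$label)) timings$label <- "problem"
    out <- lapply(split(timings, timings$label), function(tt) {
        base <- tt$wall_time[tt$worker_count == 1]
        if (length(base) != 1)
            stop("each problem needs exactly one worker_count = 1 baseline row")
        tt <- tt[order(tt$worker_count), , drop = FALSE]
        tt$speedup <- base / tt$wall_time
        tt$efficiency <- tt$speedup / tt$worker_count
        tt[, c("label", "worker_count", "wall_time", "speedup", "efficiency")]
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
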