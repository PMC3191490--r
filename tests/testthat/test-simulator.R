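test_that("generator hits the requested edge count exactly and is seed-deterministic", {
    net <- generateScaleFreeNetwork(simulationConfig(1000, 3054, seed = 11))
    expect_equal(edgeCount(net), 3054)
    expect_equal(nodeCount(net), 1000)

    for (cfg in list(simulationConfig(20, 0, seed = 2),
                     simulationConfig(30, 60, seed = 3),
                     simulationConfig(12, 12 * 11, seed = 4))) {
        suppressWarnings(net <- generateScaleFreeNetwork(cfg))
        expect_equal(edgeCount(net), cfg@nEdges)
        suppressWarnings(net2 <- generateScaleFreeNetwork(cfg))
        expect_identical(weightMatrix(net), weightMatrix(net2))
    }

    # empty edge set: only diagonal self-decay remains
    net0 <- generateScaleFreeNetwork(simulationConfig(5, 0, seed = 1))
    expect_equal(edgeCount(net0), 0)
    expect_identical(weightMatrix(net0), diag(-2, 5) |>
        `dimnames<-`(list(nodeIds(net0), nodeIds(net0))))
})

test_that("generator enforces parameter feasibility and weight conventions", {
    expect_error(simulationConfig(5, 21, seed = 1), "infeasible")
    expect_error(simulationConfig(1, 1, seed = 1), "2 nodes")
    expect_warning(generateScaleFreeNetwork(simulationConfig(10, 60, seed = 1)),
                   "density")

    net <- generateScaleFreeNetwork(
        simulationConfig(40, 100, seed = 5, fractionNegative = 1,
                         selfDecay = -3))
    w <- weightMatrix(net)
    expect_true(all(diag(w) == -3))
    off <- w[row(w) != col(w)]
    off <- off[off != 0]
    expect_true(all(off < 0))  # fractionNegative = 1
    expect_true(all(abs(off) >= 0.5 & abs(off) <= 1.5))
})

test_that("total-degree distribution of generated networks is heavy-tailed", {
    # pooled binned degree counts over 20 seeds at the benchmark size;
    # independent least-squares fit of log frequency on log degree
    degs <- unlist(lapply(1:20, function(s) {
        net <- generateScaleFreeNetwork(simulationConfig(1000, 3054, seed = s))
        w <- weightMatrix(net)
        diag(w) <- 0
        rowSums(w != 0) + colSums(w != 0)
    }))
    tab <- table(degs[degs > 0])
    d <- as.numeric(names(tab))
    slope <- unname(coef(lm(log(as.numeric(tab)) ~ log(d)))[2])
    expect_gt(slope, -3.5)
    expect_lt(slope, -1.0)
})

test_that("steady-state simulation equals the exact linear solve", {
    # A = -I: X = -A^{-1} P = P
    net <- signedNetwork(diag(-1, 2), c("a", "b"))
    P <- perturbationMatrix(cbind(e1 = c(1, 0)), geneIds = c("a", "b"))
    expect_equal(unname(exprValues(simulateSteadyState(net, P))[, 1]),
                 c(1, 0))

    # homogeneous system
    P0 <- perturbationMatrix(matrix(0, 2, 3), geneIds = c("a", "b"))
    expect_true(all(exprValues(simulateSteadyState(net, P0)) == 0))

    # 10-gene network, 12 single-gene perturbation columns vs dense inverse
    truth <- generateScaleFreeNetwork(simulationConfig(10, 18, seed = 9))
    ids <- nodeIds(truth)
    P12 <- knockoutDesign(ids, targets = rep(ids[1:6], 2))
    X <- simulateSteadyState(truth, P12)
    A <- weightMatrix(truth)
    oracle <- -solve(A) %*% perturbValues(P12)  # independent dense inversion
    expect_lt(max(abs(exprValues(X) - oracle)), 1e-10)
    # steady-state consistency invariant
    expect_lt(max(abs(A %*% exprValues(X) + perturbValues(P12))), 1e-8)
})

test_that("steady-state noise is seed-reproducible and singular systems are refused", {
    net <- signedNetwork(diag(-1, 3))
    P <- knockoutDesign(nodeIds(net))
    x1 <- exprValues(simulateSteadyState(net, P, noiseSd = 0.5, seed = 7))
    x2 <- exprValues(simulateSteadyState(net, P, noiseSd = 0.5, seed = 7))
    x3 <- exprValues(simulateSteadyState(net, P, noiseSd = 0.5, seed = 8))
    expect_identical(x1, x2)
    expect_false(identical(x1, x3))

    sing <- signedNetwork(matrix(c(1, 1, 1, 1), 2), c("a", "b"))
    expect_error(simulateSteadyState(sing, perturbationMatrix(
        cbind(e1 = c(1, 0)), geneIds = c("a", "b"))), "condition")
})

test_that("Euler integration reproduces known dynamics", {
    # zero dynamics: constant trajectory
    net0 <- signedNetwork(matrix(0, 2, 2), c("a", "b"))
    x <- simulateTimeSeries(net0, x0 = c(3, -1), p = c(0, 0), dt = 0.1,
                            nSteps = 20)
    expect_true(all(exprValues(x) == c(3, -1)))

    # one gene relaxing to its fixed point x* = -p/a = 1
    net1 <- signedNetwork(matrix(-1, 1, 1), "a")
    x <- simulateTimeSeries(net1, x0 = 0, p = 1, dt = 0.01, nSteps = 2000)
    expect_lt(abs(exprValues(x)[1, 2001] - 1), 1e-3)
    expect_equal(SummarizedExperiment::colData(x)$time[2001], 20)

    # diverging system is caught with advice
    hot <- signedNetwork(matrix(5, 1, 1), "a")
    expect_error(simulateTimeSeries(hot, x0 = 1, p = 0, dt = 1,
                                    nSteps = 100), "smaller dt")
})

test_that("Euler trajectories converge to the matrix-exponential solution", {
    A <- matrix(c(-1, 0.2, 0.5, -1.2), 2)
    net <- signedNetwork(A, c("a", "b"))
    x0 <- c(1, -0.5)
    exact <- as.numeric(Matrix::expm(A * 1) %*% x0)  # independent oracle

    errAt <- function(dt) {
        x <- simulateTimeSeries(net, x0 = x0, p = c(0, 0), dt = dt,
                                nSteps = round(1 / dt))
        max(abs(exprValues(x)[, ncol(x)] - exact))
    }
    expect_lt(errAt(1e-3), 5e-3)
    # halving dt at a fixed horizon reduces the error monotonically
    errs <- vapply(c(0.02, 0.01, 0.005, 0.0025), errAt, numeric(1))
    expect_true(all(diff(errs) < 0))
})
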