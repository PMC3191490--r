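test_that("regression problems encode the steady-state balance", {
    X <- expressionDataset(matrix(rnorm(6), 2, 3), geneIds = c("g1", "g2"))
    P <- perturbationMatrix(rbind(c(-1, 0, 0), c(0, 0, 0)),
                            geneIds = c("g1", "g2"))
    pr <- buildRegressionProblems(X, P)
    # response is the negated perturbation row
    expect_equal(pr$g1$response, c(1, 0, 0))
    # the target's own expression is forced, not a candidate
    expect_identical(colnames(pr$g1$candidates), "g2")
    expect_equal(unname(pr$g1$forced[, 1]), unname(exprValues(X)["g1", ]))

    X4 <- expressionDataset(matrix(rnorm(20), 4, 5))
    P4 <- perturbationMatrix(matrix(0, 4, 5))
    pr4 <- buildRegressionProblems(X4, P4)
    expect_true(all(vapply(pr4, function(p) ncol(p$candidates), 0L) == 3))

    prSelf <- buildRegressionProblems(X4, P4, swniConfig(allowSelfEdges = TRUE))
    expect_true(all(vapply(prSelf, function(p) ncol(p$candidates), 0L) == 4))
    expect_null(prSelf$g1$forced)

    expect_error(buildRegressionProblems(X4, P), "misaligned")
})

test_that("time-series problems use central differences with one-sided ends", {
    xv <- rbind(g1 = c(0, 1, 4, 9), g2 = c(1, 1, 1, 1))
    X <- expressionDataset(xv, time = 0:3)
    P <- perturbationMatrix(matrix(0, 2, 4), geneIds = c("g1", "g2"))
    pr <- buildRegressionProblems(X, P, swniConfig(mode = "time_series"))
    expect_equal(pr$g1$response, c(1, 2, 4, 5))  # fwd, central, central, bwd

    X2 <- expressionDataset(xv[, 1:2], time = 0:1)
    expect_error(buildRegressionProblems(
        X2, perturbationMatrix(matrix(0, 2, 2), geneIds = c("g1", "g2")),
        swniConfig(mode = "time_series")), "3 timepoints")
})

test_that("stepwise selection recovers a noiseless single cause exactly", {
    set.seed(10)
    x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
    m <- forwardStepwise(2 * x[, "g1"], x)
    expect_identical(m@regulators, "g1")
    expect_lt(abs(m@coefficients - 2), 1e-10)
    expect_lt(m@pvalues, 1e-10)

    # determinism of the full path, including the step log
    m2 <- forwardStepwise(2 * x[, "g1"], x)
    expect_identical(m@steps, m2@steps)
    expect_identical(m@coefficients, m2@coefficients)
})

test_that("stepwise handles degenerate inputs as contracts, not crashes", {
    x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
    expect_error(forwardStepwise(c(1, 2), x[1:2, ]), "3 observations")

    # all-zero response: empty model, no error
    m0 <- forwardStepwise(rep(0, 10), x)
    expect_length(m0@regulators, 0)

    # zero-variance candidate is dropped and logged
    x2 <- cbind(x, flat = rep(1, 10))
    m1 <- forwardStepwise(2 * x[, "a"], x2)
    expect_true(any(m1@steps$action == "dropped_zero_variance" &
                    m1@steps$variable == "flat"))
    expect_false("flat" %in% m1@regulators)

    # perfectly collinear candidate is skipped with a log entry
    x3 <- cbind(x[, "a", drop = FALSE], dup = x[, "a"], x[, c("b", "c")])
    m2 <- forwardStepwise(3 * x[, "a"] + rnorm(10, sd = 0.01), x3)
    expect_true(any(m2@steps$action == "skipped_collinear"))
    expect_length(intersect(c("a", "dup"), m2@regulators), 1)
})

test_that("stepwise path matches a from-scratch greedy forward oracle", {
    for (s in c(3, 14, 26)) {
        set.seed(s)
        X <- matrix(rnorm(100), 20, 5,
                    dimnames = list(NULL, paste0("g", 1:5)))
        y <- 1.5 * X[, 1] + 0.6 * X[, 3] + rnorm(20, sd = 0.5)
        cfg <- swniConfig(alphaEnter = 0.05, alphaRemove = 0.99)
        m <- forwardStepwise(y, X, cfg)
        entered <- m@steps$variable[m@steps$action == "entered"]
        oracle <- oracleForwardPath(y, X, alphaEnter = 0.05)
        expect_false(any(m@steps$action == "removed"))
        expect_identical(entered, oracle)
    }
})

test_that("independent genes yield an empty network", {
    net <- signedNetwork(diag(-1, 6))
    ids <- nodeIds(net)
    P <- knockoutDesign(ids, targets = rep(ids, 2))
    X <- simulateSteadyState(net, P)
    inf <- inferNetwork(X, P)
    expect_equal(edgeCount(inf), 0)
})

test_that("noiseless inference recovers the true coefficient matrix exactly", {
    b <- makeBenchmark(n = 10, edges = 15, seed = 1, rounds = 6, noise = 0)
    inf <- inferNetwork(b$X, b$P)
    wt <- weightMatrix(b$net)
    diag(wt) <- 0
    wi <- weightMatrix(inf)
    expect_identical(unname(wi != 0), unname(wt != 0))  # support, no FP
    expect_lt(max(abs(wi - wt)), 1e-6)
    # every retained edge has a valid p-value
    el <- edgeList(inf)
    expect_true(all(el$p_value > 0 & el$p_value <= 1))
})

test_that("gene row order does not affect per-gene inference", {
    b <- makeBenchmark(n = 8, edges = 12, seed = 5, rounds = 2, noise = 0.01)
    perm <- c(4, 1, 8, 2, 7, 3, 6, 5)
    Xp <- expressionDataset(exprValues(b$X)[perm, ],
                            labels = colnames(b$X))
    Pp <- perturbationMatrix(perturbValues(b$P)[perm, ],
                             labels = colnames(b$P))
    a <- edgeList(inferNetwork(b$X, b$P))
    bb <- edgeList(inferNetwork(Xp, Pp))
    expect_equal(a, bb)
})

test_that("tightening keeps exactly the sub-alpha edges and nests monotonically", {
    w <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    p <- matrix(NA_real_, 4, 4, dimnames = dimnames(w))
    w[2, 1] <- 1;   p[2, 1] <- 0.001
    w[3, 1] <- -1;  p[3, 1] <- 0.02
    w[4, 2] <- 0.5; p[4, 2] <- 0.2
    net <- inferredNetwork(w, p)

    expect_equal(edgeCount(tightenNetwork(net, 1)), 3)
    expect_equal(edgeCount(tightenNetwork(net, 0.05)), 2)
    expect_equal(edgeCount(tightenNetwork(net, 1e-9)), 0)
    # isolated nodes are dropped
    expect_setequal(nodeIds(tightenNetwork(net, 0.05)), c("a", "b", "c"))

    # nesting over an alpha grid on an inferred fixture
    b <- makeBenchmark(n = 8, edges = 12, seed = 6, rounds = 2, noise = 0.02)
    inf <- inferNetwork(b$X, b$P, swniConfig(alphaEdge = 1))
    edgesAt <- lapply(c(1e-6, 1e-3, 0.01, 0.05, 1), function(a) {
        el <- edgeList(tightenNetwork(inf, a, dropIsolated = FALSE))
        paste(el$regulator, el$target)
    })
    for (k in seq_len(length(edgesAt) - 1))
        expect_true(all(edgesAt[[k]] %in% edgesAt[[k + 1]]))
})

test_that("evaluation computes directed confusion counts with NA for undefined rates", {
    truth <- signedNetwork(matrix(c(-1, 1, 0, -1), 2), c("a", "b"))
    perfect <- evaluateNetwork(truth, truth)
    expect_equal(perfect@sensitivity, 1)
    expect_equal(perfect@precision, 1)
    expect_equal(perfect@signAccuracy, 1)

    empty <- signedNetwork(diag(-1, 2), c("a", "b"))
    miss <- evaluateNetwork(empty, truth)
    expect_equal(miss@sensitivity, 0)
    expect_true(is.na(miss@precision))

    # 5 true edges, 6 inferred, 4 overlap on 6 nodes
    ids <- letters[1:6]
    wt <- matrix(0, 6, 6, dimnames = list(ids, ids))
    wt[cbind(2:6, 1)] <- 1                      # b..f <- a
    wi <- matrix(0, 6, 6, dimnames = list(ids, ids))
    wi[cbind(2:5, 1)] <- 1                      # 4 overlapping
    wi[1, 2] <- 1; wi[1, 3] <- 1                # 2 false
    m <- evaluateNetwork(signedNetwork(wi), signedNetwork(wt))
    expect_equal(m@tp, 4L); expect_equal(m@fp, 2L); expect_equal(m@fn, 1L)
    expect_equal(m@sensitivity, 0.8)
    expect_equal(m@precision, 4 / 6, tolerance = 1e-12)
    expect_equal(m@tp + m@fp + m@fn + m@tn, 6 * 5)

    expect_error(evaluateNetwork(truth, signedNetwork(diag(-1, 3))),
                 "symmetric difference")
})
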