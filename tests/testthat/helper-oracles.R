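# Independent reference implementations used to cross-check the package.
# These deliberately avoid the package's own code paths.

# Depth-first enumeration of all simple directed paths source -> target with
# at most maxLength edges, sorted lexicographically by node sequence.
bruteForcePaths <- function(edges, source, target, maxLength = 10) {
    adj <- split(as.character(edges$target), as.character(edges$regulator))
    out <- list()
    recurse <- function(path) {
        last <- path[length(path)]
        if (last == target && length(path) > 1) {
            out[[length(out) + 1L]] <<- path
            return(invisible(NULL))
        }
        if (length(path) - 1L >= maxLength) return(invisible(NULL))
        for (nxt in adj[[last]])
            if (!nxt %in% path) recurse(c(path, nxt))
    }
    recurse(source)
    keys <- vapply(out, paste, character(1), collapse = "\001")
    out[order(keys, method = "radix")]
}

# Step-by-step greedy forward selection recomputed from scratch with
# lm()/anova(): at each step every remaining candidate is refit and the
# smallest partial-F p-value enters while it is below alphaEnter.
oracleForwardPath <- function(y, X, alphaEnter, maxSteps = ncol(X)) {
    df <- data.frame(.y = y, as.data.frame(X))
    selected <- character(0)
    while (length(selected) < maxSteps) {
        pool <- setdiff(colnames(X), selected)
        if (!length(pool)) break
        f0 <- stats::lm(stats::reformulate(
            if (length(selected)) selected else "1", ".y"), data = df)
        ps <- vapply(pool, function(v) {
            f1 <- stats::lm(stats::reformulate(c(selected, v), ".y"),
                            data = df)
            stats::anova(f0, f1)$`Pr(>F)`[2]
        }, numeric(1))
        ps <- sort(ps)  # ties broken lexicographically by sort()
        if (ps[1] < alphaEnter) selected <- c(selected, names(ps)[1])
        else break
    }
    selected
}

# Synthetic fixture mirroring a two-layer merged network with 39 genes,
# 66 regulatory edges, 29 proteins and 32 interactions (all nodes covered).
makeMergeFixture <- function() {
    genes <- sprintf("gene%02d", 1:39)
    reg <- data.frame(regulator = genes[1:38], target = genes[2:39],
                      stringsAsFactors = FALSE)  # chain covers all genes
    extra <- data.frame(regulator = rep(genes[1:4], each = 7),
                        target = genes[c(6:12, 14:20, 22:28, 30:36)],
                        stringsAsFactors = FALSE)
    reg <- rbind(reg, extra)  # 38 + 28 = 66 distinct directed edges
    prots <- sprintf("PROT%02d", 1:29)
    ppi <- data.frame(a = prots[1:28], b = prots[2:29],
                      stringsAsFactors = FALSE)  # chain covers all proteins
    ppi <- rbind(ppi, data.frame(a = prots[1], b = prots[c(3, 5, 7, 9)]))
    list(reg = reg, ppi = ppi)  # 28 + 4 = 32 distinct interactions
}

# Edge set reconstructed from the four regulatory cascades reaching tmem59.
nscGn4Edges <- function() {
    data.frame(
        regulator = c("pou6f1", "cd59a", "pou6f1", "sncg", "pou6f1",
                      "wfdc2", "rnd3", "mgp", "myrip", "rnd3"),
        target = c("cd59a", "tmem59", "sncg", "tmem59", "wfdc2",
                   "rnd3", "mgp", "myrip", "tmem59", "sncg"),
        stringsAsFactors = FALSE)
}

# Small deterministic benchmark problem shared across tests.
makeBenchmark <- function(n = 10, edges = 15, seed = 1, rounds = 2,
                          noise = 0) {
    cfg <- simulationConfig(n, edges, seed = seed, noiseSd = noise)
    net <- generateScaleFreeNetwork(cfg)
    ids <- nodeIds(net)
    P <- knockoutDesign(ids, targets = rep(ids, rounds))
    X <- simulateSteadyState(net, P, noiseSd = noise, seed = seed + 1000L)
    list(net = net, P = P, X = X)
}
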