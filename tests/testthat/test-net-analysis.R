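test_that("average degree is edges over nodes, raw and rounded", {
    # 56 nodes / 230 edges: average degree 4.107, i.e. 4 at integer precision
    nodes56 <- sprintf("n%02d", 1:56)
    set.seed(1)
    el <- expand.grid(regulator = nodes56, target = nodes56,
                      stringsAsFactors = FALSE)
    el <- el[el$regulator != el$target, ]
    el230 <- el[sample(nrow(el), 230), ]
    ds <- degreeSummary(el230, nodes = nodes56)
    expect_equal(ds$nEdges, 230)
    expect_equal(ds$averageDegree, 230 / 56)
    expect_equal(round(ds$averageDegree), 4)

    # 68 nodes / 98 edges -> 1.4; 37 nodes / 46 edges -> 1.2
    expect_equal(round(98 / 68, 1), 1.4)
    ds2 <- degreeSummary(el[sample(nrow(el), 98), ], nodes = sprintf("n%02d", 1:68))
    expect_equal(ds2$averageDegreeRounded, 1.4)
    ds3 <- degreeSummary(el[sample(nrow(el), 46), ], nodes = sprintf("n%02d", 1:37))
    expect_equal(ds3$averageDegreeRounded, 1.2)

    # empty edge set
    none <- degreeSummary(el230[0, ], nodes = c("a", "b"))
    expect_equal(none$averageDegree, 0)
    expect_error(degreeSummary(el230[0, ], nodes = character(0)), "no nodes")
})

test_that("hub identification uses strict in-degree thresholds", {
    star <- data.frame(regulator = c("b", "c", "d", "e"),
                       target = "hub", stringsAsFactors = FALSE)
    expect_identical(identifyHubs(star, multiplier = 1)$node, "hub")
    expect_identical(identifyHubs(star, multiplier = 0)$node, "hub")

    # in-degrees (6, 4, 1, 1, 0) on 5 nodes, 12 edges: average 2.4
    el <- rbind(
        data.frame(regulator = sprintf("s%d", 1:6), target = "n1"),
        data.frame(regulator = sprintf("s%d", 1:4), target = "n2"),
        data.frame(regulator = "n1", target = "n3"),
        data.frame(regulator = "n2", target = "n4"))
    nodes <- c("n1", "n2", "n3", "n4", "n5")
    ds <- degreeSummary(el, nodes = nodes)
    expect_equal(ds$averageDegree, 12 / 5)
    hubs2 <- identifyHubs(el, multiplier = 2, nodes = nodes)
    expect_identical(hubs2$node, "n1")  # only 6 > 4.8
    hubs1 <- identifyHubs(el, multiplier = 1, nodes = nodes)
    expect_identical(hubs1$node, c("n1", "n2"))  # sorted by in-degree
})

test_that("the four regulatory cascades into tmem59 are enumerated exactly", {
    paths <- findDirectedPaths(nscGn4Edges(), "pou6f1", "tmem59")
    expect_length(paths, 4)
    expect_identical(paths, list(
        c("pou6f1", "cd59a", "tmem59"),
        c("pou6f1", "sncg", "tmem59"),
        c("pou6f1", "wfdc2", "rnd3", "mgp", "myrip", "tmem59"),
        c("pou6f1", "wfdc2", "rnd3", "sncg", "tmem59")))
})

test_that("path enumeration matches a brute-force oracle on small digraphs", {
    empty <- data.frame(regulator = character(0), target = character(0))
    expect_length(findDirectedPaths(empty, "a", "b", maxLength = 3), 0)

    # complete digraph on 4 nodes: 1 + 2 + 2 = 5 simple paths a -> d
    k4 <- expand.grid(regulator = letters[1:4], target = letters[1:4],
                      stringsAsFactors = FALSE)
    k4 <- k4[k4$regulator != k4$target, ]
    expect_length(findDirectedPaths(k4, "a", "d", maxLength = 4), 5)

    # exhaustive sweep: random digraphs on up to 7 nodes vs the DFS oracle
    set.seed(99)
    for (rep in 1:25) {
        n <- sample(3:7, 1)
        nodes <- letters[1:n]
        all <- expand.grid(regulator = nodes, target = nodes,
                           stringsAsFactors = FALSE)
        all <- all[all$regulator != all$target, ]
        el <- all[runif(nrow(all)) < 0.35, ]
        maxLen <- sample(2:6, 1)
        got <- findDirectedPaths(el, nodes[1], nodes[n], maxLength = maxLen,
                                 nodes = nodes)
        want <- bruteForcePaths(el, nodes[1], nodes[n], maxLength = maxLen)
        expect_identical(got, want)
    }

    expect_warning(p <- findDirectedPaths(k4, "a", "a"), "cycles")
    expect_length(p, 0)
    expect_error(findDirectedPaths(k4, "zz", "a"), "source")
})

test_that("merging regulations with protein interactions conserves counts", {
    fx <- makeMergeFixture()
    cn <- mergePpi(fx$reg, fx$ppi)
    expect_equal(length(cn@genes), 39)
    expect_equal(length(cn@proteins), 29)
    expect_equal(nodeCount(cn), 68)
    expect_equal(nrow(cn@regulatoryEdges), 66)
    expect_equal(nrow(cn@interactionEdges), 32)
    expect_equal(edgeCount(cn), 98)

    # empty PPI: the combined network is just the typed GRN
    cn0 <- mergePpi(fx$reg, fx$ppi[0, ])
    expect_equal(nodeCount(cn0), 39)
    expect_equal(edgeCount(cn0), 66)

    # A-B and B-A collapse to one undirected interaction
    dup <- data.frame(a = c("P1", "P2"), b = c("P2", "P1"))
    cn1 <- mergePpi(fx$reg, dup)
    expect_equal(nrow(cn1@interactionEdges), 1)
    expect_equal(unname(cn1@metadata$duplicates["interaction"]), 1L)

    # identifier collision between spaces is refused
    expect_error(mergePpi(fx$reg, data.frame(a = "gene01", b = "P1")),
                 "both gene and protein")

    # gene -> protein map translates interaction endpoints
    mapped <- mergePpi(fx$reg,
                       data.frame(a = "gene01", b = "gene02"),
                       geneProteinMap = data.frame(
                           gene = c("gene01", "gene02"),
                           protein = c("PA", "PB")))
    expect_setequal(mapped@proteins, c("PA", "PB"))
})

test_that("localization summaries report counts and one-decimal percentages", {
    ann <- data.frame(
        gene = sprintf("g%02d", 1:27),
        localization = c(rep("plasma", 4), rep("membrane", 1),
                         rep("nucleus", 2), rep("extracellular", 4),
                         rep("other", 16)),
        stringsAsFactors = FALSE)
    genes <- sprintf("g%02d", 1:37)  # 10 of 37 are unannotated
    s <- localizationSummary(genes, ann)
    expect_equal(sum(s$count), 37)
    expect_equal(s$percentage[s$category == "plasma"], 10.8)
    expect_equal(s$percentage[s$category == "extracellular"], 10.8)
    expect_equal(s$percentage[s$category == "membrane"], 2.7)
    expect_equal(s$count[s$category == "unknown"], 10)
    expect_equal(s$percentage[s$category == "unknown"], 27.0)
    expect_lt(abs(sum(s$percentage) - 100), 0.2)

    one <- localizationSummary(c("a", "b"), data.frame(
        gene = c("a", "b"), localization = "nucleus"))
    expect_equal(one$percentage, 100.0)
    expect_error(localizationSummary(character(0), ann), "empty")
})

test_that("relative quantification follows 2^-ddCt and is monotone", {
    expect_equal(computeRq(20, 20, 20, 20), 1)
    expect_equal(computeRq(24, 20, 25, 20), 2)      # ddCt = -1
    expect_equal(computeRq(25.32, 20, 22, 20), 2^-3.32)
    expect_equal(round(2^-3.32, 4), 0.1001)

    # replicates are averaged per group
    expect_equal(computeRq(c(24, 24), c(20, 20), 25, 20), 2)

    # strictly decreasing in ddCt
    rqs <- vapply(seq(22, 28, by = 0.5), function(ct)
        computeRq(ct, 20, 25, 20), numeric(1))
    expect_true(all(diff(rqs) < 0))

    expect_error(computeRq(NA, 20, 25, 20), "missing")
    expect_error(computeRq(24, 20, numeric(0), 20), "missing")
})
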