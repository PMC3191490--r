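# Shared format readers/writers. Conventions for byte-stable files:
#  - every file starts with '#'-prefixed header lines (tool version,
#    subcommand, seed, parameter echo; no timestamps);
#  - floats serialized with 10 significant digits (%.10g);
#  - rows canonically ordered (lexicographic, C collation) on write;
#  - readers keep the header lines in attr(x, "header") so that
#    write(read(f)) is byte-identical to f.

.fmtNum <- function(x) sprintf("%.10g", x)

.stdHeader <- function(subcommand = NA, seed = NA, params = list()) {
    h <- sprintf("# stepnet %s",
                 as.character(utils::packageVersion("stepnet")))
    if (!is.na(subcommand)) h <- c(h, sprintf("# subcommand=%s", subcommand))
    if (!is.na(seed)) h <- c(h, sprintf("# seed=%s", seed))
    if (length(params))
        h <- c(h, sprintf("# %s=%s", names(params),
                          vapply(params, as.character, character(1))))
    h
}

.writeLines <- function(lines, path) {
    con <- file(path, open = "wb")  # fixed LF endings for byte-stable diffs
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    invisible(path)
}

.readHeaderLines <- function(path) {
    lines <- readLines(path)
    isHead <- grepl("^#", lines)
    firstBody <- which(!isHead)[1]
    if (is.na(firstBody))
        list(header = lines, body = character(0))
    else
        list(header = lines[seq_len(firstBody - 1)],
             body = lines[firstBody:length(lines)])
}

.headerOf <- function(x, default) {
    h <- attr(x, "header")
    if (is.null(h)) default else h
}

#' Write / read a network edge list as TSV
#'
#' Columns: regulator, target, weight (plus p_value and sign for inferred
#' networks). Rows sorted lexicographically by regulator then target, floats
#' with 10 significant digits; the result of [readEdgeListTSV()] carries the
#' original header so that a write/read/write cycle is byte-identical.
#'
#' @param net a [SignedNetwork-class], [InferredNetwork-class] or edge
#'   data.frame.
#' @param path output file.
#' @param header character vector of '#' header lines, or NULL for the
#'   standard header.
#' @param subcommand,seed,params fields for the standard header.
#' @return \code{path}, invisibly.
#' @export
writeEdgeListTSV <- function(net, path, header = NULL, subcommand = "infer",
                             seed = NA, params = list()) {
    el <- if (is.data.frame(net)) net else edgeList(net)
    if (is.null(header)) header <- .headerOf(net, NULL)
    if (is.null(header)) header <- .stdHeader(subcommand, seed, params)
    el <- el[order(el$regulator, el$target, method = "radix"), , drop = FALSE]
    numCols <- vapply(el, is.numeric, logical(1))
    body <- do.call(paste, c(lapply(seq_along(el), function(j)
        if (numCols[j]) .fmtNum(el[[j]]) else as.character(el[[j]])),
        sep = "\t"))
    .writeLines(c(header, paste(names(el), collapse = "\t"), body), path)
}

#' @rdname writeEdgeListTSV
#' @return \code{readEdgeListTSV}: data.frame of edges with the file header
#'   in \code{attr(x, "header")}.
#' @export
readEdgeListTSV <- function(path) {
    parts <- .readHeaderLines(path)
    if (length(parts$body) < 1)
        stop("malformed edge list (no column header line): ", path)
    cols <- strsplit(parts$body[1], "\t", fixed = TRUE)[[1]]
    rows <- parts$body[-1]
    if (length(rows)) {
        split <- strsplit(rows, "\t", fixed = TRUE)
        bad <- which(lengths(split) != length(cols))
        if (length(bad))
            stop(sprintf("malformed edge list at line %d of %s",
                         length(parts$header) + 1L + bad[1], path))
        df <- as.data.frame(do.call(rbind, split), stringsAsFactors = FALSE)
    } else {
        df <- as.data.frame(matrix(character(0), 0, length(cols)),
                            stringsAsFactors = FALSE)
    }
    names(df) <- cols
    for (nm in intersect(c("weight", "p_value"), cols))
        df[[nm]] <- as.numeric(df[[nm]])
    if ("sign" %in% cols) df$sign <- as.integer(df$sign)
    attr(df, "header") <- parts$header
    df
}

#' Reconstruct an InferredNetwork from an edge-list data.frame
#'
#' @param edges data.frame with regulator, target, weight, and optionally
#'   p_value columns (as written by [writeEdgeListTSV()]).
#' @param nodes node universe; defaults to the edge endpoints.
#' @return An [InferredNetwork-class] (p-value 1 where absent).
#' @export
edgesToNetwork <- function(edges, nodes = NULL) {
    if (is.null(nodes))
        nodes <- sort(unique(c(edges$regulator, edges$target)),
                      method = "radix")
    n <- length(nodes)
    w <- matrix(0, n, n, dimnames = list(nodes, nodes))
    p <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
    if (nrow(edges)) {
        idx <- cbind(match(edges$target, nodes), match(edges$regulator, nodes))
        w[idx] <- if ("weight" %in% names(edges)) edges$weight else 1
        p[idx] <- if ("p_value" %in% names(edges)) edges$p_value else 1
    }
    inferredNetwork(w, p, nodes)
}

#' Write / read a network in SIF format
#'
#' Simple interaction format: \code{source relation target}, one edge per
#' line, tab-separated. The relation is \code{activates} / \code{represses}
#' by coefficient sign (\code{regulates} when no weight is available).
#'
#' @inheritParams writeEdgeListTSV
#' @export
writeSIF <- function(net, path, header = NULL) {
    el <- if (is.data.frame(net)) net else edgeList(net)
    if (is.null(header)) header <- .headerOf(net, character(0))
    rel <- if ("relation" %in% names(el)) el$relation
    else if ("weight" %in% names(el))
        ifelse(el$weight > 0, "activates",
               ifelse(el$weight < 0, "represses", "regulates"))
    else rep("regulates", nrow(el))
    el <- data.frame(regulator = el$regulator, relation = rel,
                     target = el$target, stringsAsFactors = FALSE)
    el <- el[order(el$regulator, el$target, method = "radix"), , drop = FALSE]
    .writeLines(c(header,
                  paste(el$regulator, el$relation, el$target, sep = "\t")),
                path)
}

#' @rdname writeSIF
#' @return \code{readSIF}: data.frame (regulator, relation, target).
#' @export
readSIF <- function(path) {
    parts <- .readHeaderLines(path)
    rows <- parts$body
    split <- strsplit(rows, "\t", fixed = TRUE)
    bad <- which(lengths(split) != 3)
    if (length(bad))
        stop(sprintf("malformed SIF at line %d of %s",
                     length(parts$header) + bad[1], path))
    df <- if (length(rows))
        stats::setNames(as.data.frame(do.call(rbind, split),
                                      stringsAsFactors = FALSE),
                        c("regulator", "relation", "target"))
    else data.frame(regulator = character(0), relation = character(0),
                    target = character(0), stringsAsFactors = FALSE)
    attr(df, "header") <- parts$header
    df
}

#' Write / read expression-style matrices as TSV
#'
#' Gene rows, experiment columns, one header row (\code{gene_id} then
#' labels); optional time values in a \code{# time=} header line.
#'
#' @param x an [ExpressionDataset-class], [PerturbationMatrix-class] or
#'   numeric matrix with dimnames.
#' @inheritParams writeEdgeListTSV
#' @export
writeMatrixTSV <- function(x, path, header = NULL, subcommand = "simulate",
                           seed = NA, params = list()) {
    time <- NULL
    if (is(x, "ExpressionDataset")) {
        time <- colData(x)$time
        m <- exprValues(x)
    } else if (is(x, "PerturbationMatrix")) {
        m <- perturbValues(x)
    } else m <- as.matrix(x)
    if (is.null(header)) header <- .headerOf(x, NULL)
    if (is.null(header)) {
        header <- .stdHeader(subcommand, seed, params)
        if (!is.null(time))
            header <- c(header,
                        paste0("# time=", paste(.fmtNum(time), collapse = ",")))
    }
    lines <- c(header,
               paste(c("gene_id", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i)
                   paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = "\t"),
                   character(1)))
    .writeLines(lines, path)
}

#' @rdname writeMatrixTSV
#' @param as return type: a plain matrix, an ExpressionDataset or a
#'   PerturbationMatrix.
#' @return \code{readMatrixTSV}: the requested representation with the file
#'   header in \code{attr(,"header")} (on the matrix) or metadata.
#' @export
readMatrixTSV <- function(path, as = c("matrix", "expression",
                                       "perturbation")) {
    as <- match.arg(as)
    parts <- .readHeaderLines(path)
    if (length(parts$body) < 1)
        stop("malformed matrix file (missing header row): ", path)
    cols <- strsplit(parts$body[1], "\t", fixed = TRUE)[[1]]
    if (length(cols) < 2)
        stop("malformed matrix file (no experiment columns): ", path)
    rows <- parts$body[-1]
    split <- strsplit(rows, "\t", fixed = TRUE)
    bad <- which(lengths(split) != length(cols))
    if (length(bad))
        stop(sprintf("malformed matrix file at line %d of %s",
                     length(parts$header) + 1L + bad[1], path))
    geneIds <- vapply(split, `[`, character(1), 1)
    m <- matrix(NA_real_, length(rows), length(cols) - 1,
                dimnames = list(geneIds, cols[-1]))
    for (i in seq_along(split))
        m[i, ] <- as.numeric(split[[i]][-1])
    timeLine <- grep("^# time=", parts$header, value = TRUE)
    time <- if (length(timeLine))
        as.numeric(strsplit(sub("^# time=", "", timeLine[1]), ",")[[1]])
    else NULL
    if (as == "matrix") {
        attr(m, "header") <- parts$header
        return(m)
    }
    out <- if (as == "expression")
        expressionDataset(m, time = time)
    else perturbationMatrix(m)
    metadata(out)$header <- parts$header
    out
}

#' Write / read a directed network in Pajek .net format
#'
#' Minimal Pajek dialect: \code{*Vertices n} with quoted labels, then
#' \code{*Arcs} with 1-based vertex indices and %.10g weights. Node order is
#' the network's node order.
#'
#' @inheritParams writeEdgeListTSV
#' @export
writePajek <- function(net, path, header = NULL) {
    if (is.data.frame(net)) {
        nodes <- .netNodes(net, net)
        el <- net
    } else {
        nodes <- nodeIds(net)
        el <- edgeList(net)
    }
    idx <- stats::setNames(seq_along(nodes), nodes)
    lines <- c(sprintf("*Vertices %d", length(nodes)),
               sprintf("%d \"%s\"", seq_along(nodes), nodes),
               "*Arcs",
               if (nrow(el)) sprintf("%d %d %s", idx[el$regulator],
                                     idx[el$target],
                                     .fmtNum(if ("weight" %in% names(el))
                                         el$weight else rep(1, nrow(el)))))
    .writeLines(lines, path)
}

#' @rdname writeEdgeListTSV
#' @return \code{readPajek}: a [SignedNetwork-class].
#' @export
readPajek <- function(path) {
    lines <- readLines(path)
    vHead <- grep("^\\*Vertices", lines, ignore.case = TRUE)
    aHead <- grep("^\\*Arcs", lines, ignore.case = TRUE)
    if (length(vHead) != 1 || length(aHead) != 1)
        stop("malformed Pajek file (need *Vertices and *Arcs sections): ",
             path)
    nv <- as.integer(sub("^\\*Vertices\\s+", "", lines[vHead],
                         ignore.case = TRUE))
    vLines <- lines[(vHead + 1):(vHead + nv)]
    labels <- sub('^\\s*\\d+\\s+"(.*)"\\s*$', "\\1", vLines)
    w <- matrix(0, nv, nv, dimnames = list(labels, labels))
    aLines <- if (aHead < length(lines))
        lines[(aHead + 1):length(lines)] else character(0)
    aLines <- aLines[nzchar(trimws(aLines))]
    for (ln in aLines) {
        f <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(f) < 2) stop("malformed Pajek arc line: ", ln)
        from <- as.integer(f[1]); to <- as.integer(f[2])
        weight <- if (length(f) >= 3) as.numeric(f[3]) else 1
        w[to, from] <- weight
    }
    signedNetwork(w, labels)
}

#' Export a CombinedNetwork to GraphML
#'
#' Node type (gene/protein) and edge provenance (regulatory/interaction)
#' are carried as attributes; regulatory edges are directed, interactions
#' are stored as symmetric pairs. Uses \code{igraph::write_graph}.
#'
#' @param net a [CombinedNetwork-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGraphML <- function(net, path) {
    stopifnot(is(net, "CombinedNetwork"))
    re <- net@regulatoryEdges
    ie <- net@interactionEdges
    edges <- rbind(
        data.frame(from = re$from, to = re$to, provenance = re$provenance,
                   stringsAsFactors = FALSE),
        data.frame(from = ie$a, to = ie$b, provenance = ie$provenance,
                   stringsAsFactors = FALSE),
        if (nrow(ie)) data.frame(from = ie$b, to = ie$a,
                                 provenance = ie$provenance,
                                 stringsAsFactors = FALSE))
    vertices <- data.frame(
        name = c(net@genes, net@proteins),
        type = c(rep("gene", length(net@genes)),
                 rep("protein", length(net@proteins))),
        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = vertices)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

#' Write / read a flat JSON configuration
#'
#' @param config named list of scalar settings.
#' @param path file path.
#' @return \code{readConfigJSON}: named list.
#' @export
writeConfigJSON <- function(config, path) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeConfigJSON
#' @export
readConfigJSON <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a timing table or scaling report as TSV
#'
#' @param df data.frame (e.g. from [benchmarkScaling()] or
#'   [speedupEfficiency()]).
#' @inheritParams writeEdgeListTSV
#' @export
writeTableTSV <- function(df, path, header = NULL, subcommand = "benchmark",
                          seed = NA, params = list()) {
    if (is.null(header)) header <- .stdHeader(subcommand, seed, params)
    numCols <- vapply(df, is.numeric, logical(1))
    body <- do.call(paste, c(lapply(seq_along(df), function(j)
        if (numCols[j]) .fmtNum(df[[j]]) else as.character(df[[j]])),
        sep = "\t"))
    .writeLines(c(header, paste(names(df), collapse = "\t"), body), path)
}
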