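#' Average Difference of a probe set
#'
#' Mean of the perfect-match minus mismatch intensity differences across the
#' probe pairs of one probe set: \code{mean(pm - mm)}. Higher expression
#' gives a larger Average Difference, so it doubles as a probe-set level
#' expression score.
#'
#' @param pm,mm numeric vectors of equal length (>= 1) of perfect-match and
#'   mismatch intensities.
#' @return numeric scalar.
#' @examples
#' averageDifference(c(10, 12, 14), c(1, 2, 3))  # 10
#' @export
averageDifference <- function(pm, mm) {
    if (length(pm) != length(mm))
        stop("pm and mm must have equal length")
    if (length(pm) < 1) stop("at least one probe pair is required")
    mean(pm - mm)
}

#' Map probe-set rows to gene rows
#'
#' Each probe set is assigned to the first gene in its annotation list (the
#' first identifier is typically the curated one). When several probe sets
#' map to the same gene, the gene row is either the probe set with the
#' largest Average Difference (\code{summarize = "maxAD"}, the default) or
#' the mean across its probe sets (\code{summarize = "mean"}). Unmapped
#' probe sets (empty annotation) are dropped and counted.
#'
#' @param probeTable data.frame with columns \code{probe_id},
#'   \code{gene_ids} (semicolon-separated, first = primary), and one numeric
#'   column per sample.
#' @param pm,mm optional matrices of paired probe intensities (rows matching
#'   \code{probeTable}); when supplied, the Average Difference used to rank
#'   probe sets is \code{rowMeans(pm - mm)}, otherwise the mean sample
#'   intensity of the probe-set row is used as the expression score.
#' @param summarize \code{"maxAD"} or \code{"mean"}.
#' @return An [ExpressionDataset-class]; \code{metadata(x)$mappingReport}
#'   lists unmapped probe sets and the chosen representative per gene.
#' @examples
#' pt <- data.frame(probe_id = c("p1", "p2"),
#'                  gene_ids = c("GeneA;GeneB", "GeneC"),
#'                  s1 = c(1, 2), s2 = c(3, 4))
#' geneIds <- rownames(mapProbesToGenes(pt))  # "GeneA" "GeneC"
#' @export
mapProbesToGenes <- function(probeTable, pm = NULL, mm = NULL,
                             summarize = c("maxAD", "mean")) {
    summarize <- match.arg(summarize)
    stopifnot(is.data.frame(probeTable),
              all(c("probe_id", "gene_ids") %in% names(probeTable)))
    if (!nrow(probeTable)) stop("empty probe table")
    sampleCols <- setdiff(names(probeTable), c("probe_id", "gene_ids"))
    if (!length(sampleCols)) stop("no sample columns in probe table")
    gidList <- strsplit(trimws(as.character(probeTable$gene_ids)), ";")
    first <- vapply(gidList, function(g) {
        g <- trimws(g[nzchar(trimws(g))])
        if (length(g)) g[1] else NA_character_
    }, character(1))
    unmapped <- probeTable$probe_id[is.na(first)]
    keep <- !is.na(first)
    if (!any(keep)) stop("all probe sets are unmapped")
    tab <- probeTable[keep, , drop = FALSE]
    gene <- first[keep]
    vals <- as.matrix(tab[, sampleCols, drop = FALSE])
    score <- if (!is.null(pm) && !is.null(mm)) {
        if (nrow(as.matrix(pm)) != nrow(probeTable))
            stop("pm/mm rows must match the probe table")
        rowMeans(as.matrix(pm) - as.matrix(mm))[keep]
    } else rowMeans(vals)
    chosen <- character(0)
    rows <- lapply(split(seq_along(gene), gene), function(idx) {
        if (summarize == "mean" && length(idx) > 1) {
            chosen <<- c(chosen, NA_character_)
            colMeans(vals[idx, , drop = FALSE])
        } else {
            best <- idx[order(-score[idx], tab$probe_id[idx])[1]]
            chosen <<- c(chosen, tab$probe_id[best])
            vals[best, ]
        }
    })
    out <- do.call(rbind, rows)
    ds <- expressionDataset(out, geneIds = names(rows), labels = sampleCols)
    metadata(ds)$mappingReport <- list(
        nUnmapped = length(unmapped), unmappedProbes = unmapped,
        representative = stats::setNames(chosen, names(rows)),
        summarize = summarize)
    ds
}

#' Quantile-normalize an expression dataset
#'
#' Forces every sample column onto the identical distribution: the mean of
#' the order statistics across columns (ties averaged by rank). Delegates to
#' \code{limma::normalizeQuantiles}. Optionally log2-transforms intensities
#' (with pseudocount 1) first, the usual variance stabilization before
#' normalizing raw intensities. Idempotent on already-normalized data.
#'
#' @param dataset an [ExpressionDataset-class] with >= 2 samples (a single
#'   sample is returned unchanged with a warning).
#' @param log2Transform apply \code{log2(x + 1)} before normalizing.
#' @return An [ExpressionDataset-class].
#' @examples
#' d <- expressionDataset(cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6)))
#' exprValues(quantileNormalize(d))  # both columns 2.5, 3.5, 4.5
#' @export
quantileNormalize <- function(dataset, log2Transform = FALSE) {
    stopifnot(is(dataset, "ExpressionDataset"))
    v <- exprValues(dataset)
    if (log2Transform) v <- log2(v + 1)
    if (ncol(v) < 2) {
        warning("single sample: quantile normalization skipped")
        out <- v
    } else {
        out <- limma::normalizeQuantiles(v, ties = TRUE)
        dimnames(out) <- dimnames(v)
    }
    res <- expressionDataset(out, geneIds = rownames(v), labels = colnames(v))
    metadata(res) <- metadata(dataset)
    res
}

#' Remove batch effects by per-gene, per-batch mean-centering
#'
#' Subtracts from every gene row the within-batch mean, so that after
#' adjustment each gene has mean 0 inside every batch and the batches are
#' intermixed on a common level. A batch with a single sample is centered to
#' exactly zero (warned, since its biological signal is removed with the
#' batch mean).
#'
#' @param dataset an [ExpressionDataset-class].
#' @param batches character/factor vector of batch labels, one per sample.
#' @return An [ExpressionDataset-class].
#' @examples
#' d <- expressionDataset(matrix(c(1, 3, 10, 14), 1))
#' exprValues(batchMeanCenter(d, c("b1", "b1", "b2", "b2")))  # -1 1 -2 2
#' @export
batchMeanCenter <- function(dataset, batches) {
    stopifnot(is(dataset, "ExpressionDataset"))
    v <- exprValues(dataset)
    batches <- as.character(batches)
    if (length(batches) != ncol(v))
        stop("every sample needs a batch label")
    if (any(table(batches) == 1))
        warning("batch with a single sample: its values are centered to zero")
    for (b in unique(batches)) {
        idx <- which(batches == b)
        v[, idx] <- v[, idx, drop = FALSE] -
            rowMeans(v[, idx, drop = FALSE])
    }
    res <- expressionDataset(v, geneIds = rownames(v), labels = colnames(v))
    metadata(res) <- metadata(dataset)
    res$batch <- batches
    res
}

#' Combine expression datasets into a composite training set
#'
#' Restricts all datasets to their common gene set (rows in the first
#' dataset's order), concatenates the sample columns in input order, and
#' labels each sample with its source dataset (the batch). Dropped genes
#' are reported per dataset in the metadata.
#'
#' @param datasets list of [ExpressionDataset-class] (>= 1).
#' @return An [ExpressionDataset-class] whose \code{colData} carries the
#'   \code{batch} label; \code{metadata(x)$combineReport} lists dropped
#'   genes per dataset.
#' @examples
#' d1 <- expressionDataset(matrix(1:6, 3), geneIds = c("A", "B", "C"))
#' d2 <- expressionDataset(matrix(1:4, 2), geneIds = c("B", "C"))
#' rownames(combineDatasets(list(d1, d2)))  # "B" "C"
#' @export
combineDatasets <- function(datasets) {
    stopifnot(is.list(datasets), length(datasets) >= 1)
    stopifnot(all(vapply(datasets, is, logical(1), "ExpressionDataset")))
    nms <- names(datasets)
    if (is.null(nms) || any(!nzchar(nms)))
        nms <- paste0("d", seq_along(datasets))
    common <- Reduce(intersect, lapply(datasets, rownames))
    if (!length(common))
        stop("empty gene intersection across datasets")
    dropped <- lapply(datasets, function(d) setdiff(rownames(d), common))
    names(dropped) <- nms
    mats <- lapply(seq_along(datasets), function(i) {
        m <- exprValues(datasets[[i]])[common, , drop = FALSE]
        colnames(m) <- paste(nms[i], colnames(m), sep = ".")
        m
    })
    combined <- do.call(cbind, mats)
    batch <- rep(nms, vapply(datasets, ncol, integer(1)))
    res <- expressionDataset(combined, geneIds = common,
                             labels = colnames(combined))
    res$batch <- batch
    metadata(res)$combineReport <- list(droppedGenes = dropped)
    res
}
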