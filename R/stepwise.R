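# Per-gene stepwise regression under the steady-state linear model.
# Numerical conventions:
#  - candidates are standardized (zero mean, unit variance) before selection;
#    coefficients are reported back on the original scale;
#  - entry/removal use the partial F-test (equivalently the t-test on the
#    added coefficient);
#  - a residual sum of squares below .rssTol * baseline counts as a perfect
#    fit: no further F statistics are computable, selection stops, and
#    coefficients numerically indistinguishable from zero get p = 1 so the
#    removal phase can discard them.

.rssTol <- 1e-10
.pFloor <- 1e-300

.fitOls <- function(y, Z) {
    # least squares via QR; Z includes the intercept column
    fit <- stats::lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    list(coef = fit$coefficients, rss = rss, rank = fit$rank, qr = fit$qr)
}

.coefPvalues <- function(y, Z, baseline) {
    # two-sided t-test p-values for each column of Z (intercept first)
    fit <- .fitOls(y, Z)
    k <- ncol(Z)
    df <- length(y) - k
    if (fit$rank < k || df < 1)
        return(list(coef = fit$coef, p = rep(NA_real_, k), rss = fit$rss))
    if (fit$rss <= .rssTol * baseline) {
        scale <- sqrt(baseline / length(y)) + .Machine$double.eps
        p <- ifelse(abs(fit$coef) < 1e-8 * scale, 1, .pFloor)
        return(list(coef = fit$coef, p = p, rss = fit$rss))
    }
    XtXinv <- chol2inv(qr.R(fit$qr))
    se <- rep(NA_real_, k)
    se[fit$qr$pivot] <- sqrt(diag(XtXinv) * fit$rss / df)  # undo QR pivoting
    tval <- fit$coef / se
    p <- 2 * stats::pt(-abs(tval), df)
    p <- pmax(p, .pFloor)
    list(coef = fit$coef, p = p, rss = fit$rss)
}

.partialFp <- function(rssSmall, rssBig, dfResidBig, baseline) {
    # p-value for adding one regressor (partial F with 1 numerator df)
    if (dfResidBig < 1) return(NA_real_)
    if (rssBig <= .rssTol * baseline) {
        if (rssSmall <= .rssTol * baseline) return(1)
        return(.pFloor)
    }
    F <- max(0, (rssSmall - rssBig)) / (rssBig / dfResidBig)
    max(stats::pf(F, 1, dfResidBig, lower.tail = FALSE), .pFloor)
}

#' Forward/backward stepwise regulator selection for one target gene
#'
#' Classic stepwise least squares: at each step the candidate with the
#' smallest partial-F p-value enters if it is below \code{alphaEnter}; after
#' each entry any included variable whose coefficient p-value is at or above
#' \code{alphaRemove} is removed (worst first); selection stops when nothing
#' changes, the fit is numerically perfect, the residual degrees of freedom
#' are exhausted, or \code{maxRegulators} is reached. Ties on the entry
#' p-value are broken by larger absolute (standardized) coefficient, then by
#' lexicographic candidate id, making the path fully deterministic.
#'
#' Candidates are standardized internally; zero-variance candidates are
#' dropped beforehand and logged. An all-zero response returns an empty
#' model. Candidates perfectly collinear with the entered set are skipped
#' with a log entry.
#'
#' \code{forced} covariates are part of every fitted model from the start:
#' they are never tested, never removed, and never reported as regulators.
#' Network inference uses this to absorb the target gene's own self-decay
#' term \eqn{a_{ii} x_i}, which is part of the steady-state balance but is
#' not a reportable edge.
#'
#' @param response numeric response vector (length m >= 3).
#' @param candidates numeric matrix, m rows, one named column per candidate
#'   regulator.
#' @param config a [swniConfig()].
#' @param target label for the modelled gene (bookkeeping only).
#' @param forced optional numeric matrix (m rows) of always-included,
#'   unreported covariates.
#' @return A [SelectedModel-class] with coefficients on the original scale,
#'   per-coefficient two-sided p-values, the final residual sum of squares,
#'   and a step log.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
#' m <- forwardStepwise(2 * x[, 1], x, swniConfig())
#' m@regulators  # "g1"
#' @export
forwardStepwise <- function(response, candidates, config = swniConfig(),
                            target = "y", forced = NULL) {
    stopifnot(is(config, "SwniConfig"))
    validObject(config)
    y <- as.numeric(response)
    m <- length(y)
    if (m < 3)
        stop("at least 3 observations are required for stepwise selection")
    candidates <- as.matrix(candidates)
    if (nrow(candidates) != m)
        stop("candidate matrix rows must match the response length")
    if (is.null(colnames(candidates)))
        colnames(candidates) <- paste0("x", seq_len(ncol(candidates)))

    steps <- data.frame(action = character(0), variable = character(0),
                        pvalue = numeric(0), stringsAsFactors = FALSE)
    logStep <- function(action, variable, pvalue) {
        steps[nrow(steps) + 1L, ] <<- list(action, variable, pvalue)
    }

    sds <- apply(candidates, 2, stats::sd)
    dropped <- colnames(candidates)[sds == 0 | !is.finite(sds)]
    for (d in dropped) logStep("dropped_zero_variance", d, NA_real_)
    keep <- setdiff(colnames(candidates), dropped)
    candidates <- candidates[, keep, drop = FALSE]

    # base design: intercept plus any forced (always-included) covariates
    W0 <- cbind(`(Intercept)` = rep(1, m))
    if (!is.null(forced)) {
        forced <- as.matrix(forced)
        stopifnot(nrow(forced) == m)
        fsd <- apply(forced, 2, stats::sd)
        forced <- forced[, fsd > 0 & is.finite(fsd), drop = FALSE]
        if (ncol(forced)) W0 <- cbind(W0, scale(forced))
    }
    nBase <- ncol(W0)

    maxReg <- config@maxRegulators
    if (is.na(maxReg)) maxReg <- min(10L, m - 2L)
    maxReg <- min(maxReg, ncol(candidates))

    emptyModel <- function() new("SelectedModel", target = target,
        regulators = character(0), coefficients = numeric(0),
        pvalues = numeric(0), rss = .fitOls(y, W0)$rss, steps = steps)

    if (ncol(candidates) == 0 || all(y == 0) || maxReg < 1)
        return(emptyModel())

    mu <- colMeans(candidates)
    Z <- sweep(sweep(candidates, 2, mu), 2, sds[keep], "/")
    baseline <- max(sum((y - mean(y))^2), sum(y^2), .Machine$double.eps)

    selected <- character(0)
    iter <- 0L
    repeat {
        iter <- iter + 1L
        if (iter > 4L * (maxReg + 1L)) break  # guard against entry/removal cycling
        # ---- entry phase
        pool <- setdiff(colnames(Z), selected)
        entered <- FALSE
        dfBig <- m - (nBase + length(selected) + 1L)  # base + k + 1 slopes
        if (length(selected) < maxReg && length(pool) && dfBig >= 1) {
            Wcur <- cbind(W0, Z[, selected, drop = FALSE])
            rssCur <- .fitOls(y, Wcur)$rss
            cand <- data.frame(variable = pool, p = NA_real_,
                               absCoef = NA_real_, stringsAsFactors = FALSE)
            for (r in seq_len(nrow(cand))) {
                v <- cand$variable[r]
                W <- cbind(Wcur, Z[, v])
                fit <- .fitOls(y, W)
                if (fit$rank < ncol(W)) {
                    logStep("skipped_collinear", v, NA_real_)
                    next
                }
                cand$p[r] <- .partialFp(rssCur, fit$rss, m - ncol(W), baseline)
                cand$absCoef[r] <- abs(fit$coef[ncol(W)])
            }
            cand <- cand[!is.na(cand$p), , drop = FALSE]
            if (nrow(cand)) {
                ord <- order(cand$p, -cand$absCoef, cand$variable,
                             method = "radix")
                best <- cand[ord[1L], ]
                if (best$p < config@alphaEnter) {
                    selected <- c(selected, best$variable)
                    logStep("entered", best$variable, best$p)
                    entered <- TRUE
                }
            }
        }
        # ---- removal phase
        removedAny <- FALSE
        repeat {
            if (!length(selected)) break
            W <- cbind(W0, Z[, selected, drop = FALSE])
            ct <- .coefPvalues(y, W, baseline)
            pSlopes <- ct$p[-seq_len(nBase)]
            if (all(is.na(pSlopes))) break
            worst <- which.max(ifelse(is.na(pSlopes), -Inf, pSlopes))
            if (pSlopes[worst] >= config@alphaRemove) {
                logStep("removed", selected[worst], pSlopes[worst])
                selected <- selected[-worst]
                removedAny <- TRUE
            } else break
        }
        if (!entered && !removedAny) break
        # stop once the fit is numerically perfect
        if (length(selected)) {
            W <- cbind(W0, Z[, selected, drop = FALSE])
            if (.fitOls(y, W)$rss <= .rssTol * baseline) break
        }
    }

    if (!length(selected)) return(emptyModel())
    W <- cbind(W0, Z[, selected, drop = FALSE])
    ct <- .coefPvalues(y, W, baseline)
    coefStd <- ct$coef[-seq_len(nBase)]
    coefOrig <- as.numeric(coefStd / sds[selected])
    new("SelectedModel", target = target, regulators = selected,
        coefficients = coefOrig, pvalues = as.numeric(ct$p[-seq_len(nBase)]),
        rss = ct$rss, steps = steps)
}
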