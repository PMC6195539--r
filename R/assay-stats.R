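.lsdMatrix <- function(n, m, msw, dfW, labels) {
    k <- length(n)
    p <- matrix(1, k, k, dimnames = list(labels, labels))
    if (k < 2) return(p)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        if (msw == 0) {
            pij <- if (m[i] == m[j]) 1 else 0
        } else {
            tt <- abs(m[i] - m[j]) / sqrt(msw * (1 / n[i] + 1 / n[j]))
            pij <- 2 * stats::pt(-tt, dfW)
        }
        p[i, j] <- p[j, i] <- pij
    }
    p
}

.anovaLSD <- function(n, m, s, msb, msw, dfB, dfW, labels) {
    # a within mean square at rounding-noise level is an exact fit
    if (msw < .Machine$double.eps^0.75 * max(msb, 1)) msw <- 0
    degenerate <- msw == 0
    f <- if (degenerate) {
        if (msb == 0) 0 else Inf
    } else msb / msw
    p <- if (is.infinite(f)) 0 else stats::pf(f, dfB, dfW,
                                              lower.tail = FALSE)
    new("AnovaLSD", fStat = f, dfBetween = as.integer(dfB),
        dfWithin = as.integer(dfW), pValue = p, msWithin = msw,
        groups = data.frame(label = labels, n = n, mean = m, sd = s),
        lsdP = .lsdMatrix(n, m, msw, dfW, labels),
        degenerate = degenerate)
}

#' One-way ANOVA from group summaries (n, mean, SD)
#'
#' Reconstructs the one-way ANOVA exactly from printed group summaries:
#' the between-group mean square from group means and sizes, the
#' within-group mean square as the degrees-of-freedom-weighted mean of the
#' group variances, F on (k-1, sum(n)-k) degrees of freedom, and the full
#' Fisher LSD pairwise p-value matrix from the pooled within mean square.
#' Algebraically identical to [anovaRaw()] on raw data with the same
#' summaries. SDs are interpreted as sample standard deviations (n-1
#' denominator), the convention for "(SD)" in biology tables; set
#' `sdIsPopulation = TRUE` for the n-denominator reading.
#'
#' @param n,mean,sd numeric vectors of group sizes (each at least 2),
#'   means and standard deviations.
#' @param labels optional group labels.
#' @param sdIsPopulation interpret `sd` with the n denominator.
#' @return an [AnovaLSD-class].
#' @examples
#' # three transfection conditions, proximity-ligation spots per cell
#' anovaFromSummary(n = c(3, 3, 3), mean = c(82, 78.7, 34),
#'                  sd = c(11.3, 10.5, 5.7),
#'                  labels = c("wt/wt", "wt/mut", "mut/mut"))
#' @export
anovaFromSummary <- function(n, mean, sd, labels = NULL,
                             sdIsPopulation = FALSE) {
    k <- length(n)
    if (k < 2 || length(mean) != k || length(sd) != k)
        stop("need >= 2 groups with matching n, mean and sd")
    if (any(n < 2))
        stop("every group needs n >= 2 (within-group variance undefined)")
    if (any(sd < 0)) stop("sd must be non-negative")
    if (is.null(labels)) labels <- paste0("group", seq_len(k))
    v <- if (sdIsPopulation) sd^2 * n / (n - 1) else sd^2
    N <- sum(n)
    gm <- sum(n * mean) / N
    dfB <- k - 1L
    dfW <- N - k
    msb <- sum(n * (mean - gm)^2) / dfB
    msw <- sum((n - 1) * v) / dfW
    .anovaLSD(n, mean, sqrt(v), msb, msw, dfB, dfW, labels)
}

#' One-way ANOVA from raw replicate values
#'
#' Standard one-way decomposition (via [stats::lm()]/[stats::anova()])
#' followed by the Fisher LSD pairwise matrix. Zero within-group variance
#' is flagged degenerate (F infinite, p reported as 0).
#'
#' @param groups a named list of numeric vectors (one per group, each with
#'   at least 2 values), or a `data.frame` with columns `group` and
#'   `value`.
#' @return an [AnovaLSD-class].
#' @export
anovaRaw <- function(groups) {
    if (is.data.frame(groups)) {
        stopifnot(all(c("group", "value") %in% colnames(groups)))
        groups <- split(groups$value, groups$group)
    }
    if (length(groups) < 2) stop("need >= 2 groups")
    if (any(lengths(groups) < 2)) stop("every group needs >= 2 values")
    labels <- names(groups)
    if (is.null(labels)) labels <- paste0("group", seq_along(groups))
    d <- data.frame(value = unlist(groups, use.names = FALSE),
                    group = factor(rep(labels, lengths(groups)),
                                   levels = labels))
    at <- suppressWarnings(stats::anova(stats::lm(value ~ group, data = d)))
    msw <- at[["Mean Sq"]][2L]
    msb <- at[["Mean Sq"]][1L]
    n <- as.numeric(lengths(groups))
    m <- vapply(groups, base::mean, 0)
    s <- vapply(groups, stats::sd, 0)
    .anovaLSD(n, m, s, msb, msw, at[["Df"]][1L], at[["Df"]][2L], labels)
}

#' Pairwise Fisher LSD p-value
#'
#' Two-sided t-test of two group means using the pooled within-group mean
#' square and its degrees of freedom from a one-way ANOVA:
#' \eqn{t = |m_i - m_j| / \sqrt{MS_W (1/n_i + 1/n_j)}}. Unadjusted for
#' multiplicity, as Fisher's LSD prescribes.
#'
#' @param fit an [AnovaLSD-class] from [anovaRaw()] or
#'   [anovaFromSummary()].
#' @param i,j group labels or indices; `i == j` returns 1 by convention.
#' @return the p-value.
#' @export
lsdPairwise <- function(fit, i, j) {
    stopifnot(is(fit, "AnovaLSD"))
    lab <- fit@groups$label
    idx <- function(g) if (is.character(g)) match(g, lab) else as.integer(g)
    i <- idx(i); j <- idx(j)
    if (is.na(i) || is.na(j) || i < 1 || j < 1 ||
        i > length(lab) || j > length(lab))
        stop("unknown group")
    fit@lsdP[i, j]
}

#' Per-sample normalization of assay measurements
#'
#' Divides each raw measurement by its per-sample reference quantity
#' (e.g. an analyte concentration by the total protein of the lysate),
#' the normalization step that precedes [anovaRaw()] for enzymatic-assay
#' data.
#'
#' @param values numeric vector of raw measurements.
#' @param reference positive numeric vector of per-sample references,
#'   recycled if of length 1.
#' @return `values / reference`.
#' @export
normalizeMeasurements <- function(values, reference) {
    if (any(reference <= 0, na.rm = TRUE))
        stop("'reference' must be positive")
    values / reference
}

#' Write an ANOVA/LSD result as JSON
#'
#' @param fit an [AnovaLSD-class].
#' @param path output path.
#' @return invisibly, the list that was serialized.
#' @export
writeAnovaJson <- function(fit, path) {
    out <- list(f = fit@fStat, df_between = fit@dfBetween,
                df_within = fit@dfWithin, p = fit@pValue,
                ms_within = fit@msWithin,
                groups = fit@groups,
                lsd_p = as.data.frame(fit@lsdP),
                degenerate = fit@degenerate)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(out)
}
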