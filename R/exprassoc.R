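# Expression-matrix association layer: correlation screens with percentile
# ranking, one-tailed group tests, 2x2 factorial ANOVA.

# Accept a plain matrix or a SummarizedExperiment (first assay).
.exprMatrix <- function(x) {
    if (methods::is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x)
    if (!is.matrix(x)) x <- as.matrix(x)
    if (is.null(rownames(x))) stop("expression matrix must have gene ids as rownames")
    if (anyDuplicated(rownames(x))) stop("duplicate gene ids")
    x
}

#' Pearson correlation with a two-sided p-value
#'
#' Pearson r with the t-based two-sided p-value,
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-zero variance.
#' @return named vector \code{r}, \code{p}, \code{n}.
#' @examples
#' pearsonWithP(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
pearsonWithP <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    n <- length(x)
    if (n < 3L) stop("need at least 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in input")
    r <- stats::cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
        t <- r * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(-abs(t), df = n - 2)
    }
    c(r = r, p = p, n = n)
}

#' Percentile rank of a partner gene in a focal-gene correlation screen
#'
#' Correlates the focal gene against every other gene of the matrix, ranks
#' by descending signed r (rank 1 = strongest positive correlate), and
#' reports the partner's percentile \code{100 * rank / (genes - 1)}. No
#' multiple-testing correction is applied.
#'
#' @param mat genes x samples matrix (or \code{SummarizedExperiment}) with
#'   gene ids as rownames.
#' @param focalGene,partnerGene gene ids; they must differ.
#' @return named vector \code{r}, \code{p}, \code{percentile}, \code{rank}.
#' @export
correlationPercentile <- function(mat, focalGene, partnerGene) {
    m <- .exprMatrix(mat)
    for (g in c(focalGene, partnerGene))
        if (!g %in% rownames(m)) stop("gene not in matrix: ", g)
    if (focalGene == partnerGene)
        stop("partner must differ from the focal gene (self-correlation excluded)")
    focal <- m[focalGene, ]
    others <- setdiff(rownames(m), focalGene)
    rs <- apply(m[others, , drop = FALSE], 1L, stats::cor, y = focal)
    rk <- rank(-rs, ties.method = "min")[partnerGene]
    pw <- pearsonWithP(focal, m[partnerGene, ])
    c(r = unname(pw["r"]), p = unname(pw["p"]),
      percentile = unname(100 * rk / length(others)), rank = unname(rk))
}

#' One-tailed Welch t-test between two groups
#'
#' Welch's unequal-variance t statistic with a one-tailed p-value in the
#' stated direction.
#'
#' @param groupA,groupB numeric vectors, each with at least 2 values.
#' @param direction \code{"a>b"} or \code{"b>a"}: the alternative being
#'   tested.
#' @return named vector \code{t}, \code{p}, \code{df}.
#' @examples
#' oneTailedTTest(c(1, 2, 3), c(4, 5, 6), "b>a")
#' @export
oneTailedTTest <- function(groupA, groupB, direction = c("a>b", "b>a")) {
    direction <- match.arg(direction)
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs at least 2 values")
    alt <- if (direction == "a>b") "greater" else "less"
    tt <- stats::t.test(groupA, groupB, alternative = alt,
        var.equal = FALSE)
    c(t = unname(tt$statistic), p = tt$p.value,
      df = unname(tt$parameter))
}

#' Two-way factorial ANOVA (type-II sums of squares)
#'
#' Fits \code{value ~ f1 * f2} and reports type-II F tests per main effect
#' and the interaction, appropriate for the possibly unbalanced 2x2
#' designs of public expression datasets.
#'
#' @param values numeric response.
#' @param factor1,factor2 factors (or vectors coercible to factors) of the
#'   same length as \code{values}; every factor combination must be
#'   observed.
#' @return \code{data.frame} with rows \code{factor1}, \code{factor2},
#'   \code{interaction} and columns \code{F}, \code{p}, \code{df}.
#' @examples
#' twoWayAnova(c(1, 2, 5, 6, 1.5, 2.5, 5.5, 6.5),
#'             rep(c("a", "b"), each = 4),
#'             rep(c("x", "x", "y", "y"), 2))
#' @export
twoWayAnova <- function(values, factor1, factor2) {
    f1 <- factor(factor1); f2 <- factor(factor2)
    if (length(values) != length(f1) || length(values) != length(f2))
        stop("values and factors must have equal length")
    if (nlevels(f1) < 2L || nlevels(f2) < 2L)
        stop("each factor needs at least 2 levels")
    if (any(table(f1, f2) == 0L))
        stop("empty cell in the factorial design")
    fit <- stats::lm(values ~ f1 * f2)
    a <- car::Anova(fit, type = 2)
    idx <- c("f1", "f2", "f1:f2")
    data.frame(term = c("factor1", "factor2", "interaction"),
        F = a[idx, "F value"], p = a[idx, "Pr(>F)"],
        df = a[idx, "Df"], row.names = NULL, stringsAsFactors = FALSE)
}
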