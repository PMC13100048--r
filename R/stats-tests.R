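# Exact small-sample statistics: two-sided Fisher's exact test on 2x2
# tables and the two-tailed Mann-Whitney U test.

.testResult <- function(method, statistic, p, n, sided, exact) {
    structure(list(method = method, statistic = statistic,
                   p_value = p, n = n, sided = sided, exact = exact),
              class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
    cat(sprintf("%s (%s, %s): statistic = %.6g, p = %.4g, n = %s\n",
                x$method, x$sided, if (x$exact) "exact" else "approximate",
                x$statistic, x$p_value, paste(x$n, collapse = "/")))
    invisible(x)
}

#' Build a 2x2 contingency table
#'
#' Row convention: rows are particle classes, columns outcomes, so the
#' table is `rbind(c(a, b), c(c, d))`.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return An integer 2x2 matrix.
#' @export
contingency2x2 <- function(a, b, c, d) {
    m <- matrix(as.integer(c(a, c, b, d)), 2, 2)
    if (any(m < 0)) stop("counts must be non-negative")
    if (all(rowSums(m) == 0) || all(colSums(m) == 0))
        stop("contingency table must have a positive margin")
    m
}

#' Two-sided Fisher's exact test
#'
#' Exact two-sided p-value by probability-mass summation over all tables
#' with the observed margins (the conventional definition).  The reported
#' odds ratio is the sample odds ratio `(a*d)/(b*c)`, with `Inf` when
#' `b*c = 0` and `NaN` for a doubly-degenerate table.
#'
#' @param table a 2x2 integer matrix (see [contingency2x2()]).
#' @return A `TestResult` list: `method`, `statistic` (odds ratio),
#'   `p_value`, `n` (row totals), `sided`, `exact`.
#' @examples
#' fisherExactTwoSided(contingency2x2(80, 905, 4, 10))$p_value  # 0.0242
#' @export
fisherExactTwoSided <- function(table) {
    stopifnot(is.matrix(table), all(dim(table) == 2))
    if (any(table < 0)) stop("counts must be non-negative")
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
    or <- if (b * c > 0) (a * d) / (b * c) else if (a * d > 0) Inf else NaN
    if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
        warning("degenerate table (zero margin); p = 1")
        p <- 1
    } else {
        p <- stats::fisher.test(table, alternative = "two.sided")$p.value
    }
    .testResult("Fisher's exact test", c(odds_ratio = or), min(1, p),
                rowSums(table), "two.sided", TRUE)
}

#' Exact two-tailed Mann-Whitney U p-value from the U statistic
#'
#' Uses the exact null distribution of the U statistic (no ties).
#' `U` is the smaller of the two U values.
#'
#' @param U the smaller U statistic.
#' @param nx,ny group sizes.
#' @return two-tailed p-value.
#' @examples
#' mannWhitneyPFromU(5, 20, 20)   # < 1e-4 (Fig.-style printed U)
#' @export
mannWhitneyPFromU <- function(U, nx, ny) {
    min(1, 2 * stats::pwilcox(U, nx, ny))
}

#' Two-tailed Mann-Whitney U test
#'
#' Computes `U = min(Ux, Uy)` with midrank tie handling.  For group sizes
#' up to 25 without ties the p-value is exact (full null distribution of
#' U); otherwise a normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y numeric samples (each non-empty).
#' @return A `TestResult` list with `statistic = U`.
#' @export
mannWhitneyTwoTailed <- function(x, y) {
    if (length(x) == 0 || length(y) == 0)
        stop("both samples must contain at least one value")
    nx <- length(x); ny <- length(y)
    r <- rank(c(x, y))
    ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    uy <- nx * ny - ux
    U <- min(ux, uy)
    ties <- anyDuplicated(c(x, y)) > 0
    if (!ties && nx <= 25 && ny <= 25) {
        p <- mannWhitneyPFromU(U, nx, ny)
        exact <- TRUE
    } else {
        mu <- nx * ny / 2
        tie.tab <- table(r)
        sigma <- sqrt(nx * ny / 12 *
                      ((nx + ny + 1) -
                       sum(tie.tab^3 - tie.tab) /
                       ((nx + ny) * (nx + ny - 1))))
        if (sigma == 0) stop("all values tied; Mann-Whitney undefined")
        z <- (U - mu + 0.5) / sigma    # continuity correction toward the mean
        p <- min(1, 2 * stats::pnorm(z))
        exact <- FALSE
    }
    .testResult("Mann-Whitney U test", c(U = U), p, c(nx, ny),
                "two.sided", exact)
}

#' Compare two groups of thickness measurements
#'
#' Reports per-group medians and the two-tailed Mann-Whitney result for a
#' two-group set of measurements (see [measureGroupThickness()]).
#'
#' @param measurements a `GroupMeasurements` data.frame with columns
#'   `group` and `thickness`.
#' @return list with `medians` (named numeric) and `test` (`TestResult`).
#' @export
groupCompare <- function(measurements) {
    g <- split(measurements$thickness, measurements$group)
    if (length(g) != 2)
        stop("exactly two groups required, got ", length(g))
    med <- vapply(g, stats::median, numeric(1))
    list(medians = med, test = mannWhitneyTwoTailed(g[[1]], g[[2]]))
}
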