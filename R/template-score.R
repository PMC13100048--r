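# Desk-scale constrained cross-correlation (CCC) template scoring:
# masked, standardized zero-lag correlation of a subtomogram against a
# rotated template bank, with optional binary missing-wedge
# compensation, plus z-score peak thresholding and two-template class
# assignment.

#' Near-uniform rotation grid with Cn symmetry reduction
#'
#' Axis directions come from a spherical Fibonacci lattice at the
#' requested angular spacing; the in-plane angle about the symmetry
#' (z) axis is sampled at the same step, restricted to the fundamental
#' domain `[0, 360/symmetryOrder)`.
#'
#' @param step angular step in degrees (0 < step <= 90).
#' @param symmetryOrder Cn symmetry order (>= 1).
#' @return A `RotationGrid` list: `rotations` (3 x 3 x N), `step`,
#'   `symmetryOrder`, `nDirections`, `nInplane`.
#' @export
rotationGrid <- function(step, symmetryOrder = 1) {
    if (step <= 0 || step > 90) stop("'step' must be in (0, 90] degrees")
    if (symmetryOrder < 1) stop("'symmetryOrder' must be >= 1")
    stepRad <- step * pi / 180
    nd <- max(1L, round(4 * pi / stepRad^2))
    dirs <- fibonacciSphere(nd)
    span <- 360 / symmetryOrder
    np <- max(1L, round(span / step))
    psi <- (seq_len(np) - 1) * span / np
    rots <- array(0, c(3, 3, nd * np))
    k <- 0
    z <- c(0, 0, 1)
    for (i in seq_len(nd)) {
        Rd <- rotationFromTo(z, dirs[i, ])
        for (p in psi) {
            k <- k + 1
            rots[, , k] <- Rd %*% rotZ(p)
        }
    }
    structure(list(rotations = rots, step = step,
                   symmetryOrder = symmetryOrder,
                   nDirections = nd, nInplane = np),
              class = "RotationGrid")
}

# centred spherical mask (logical array)
.sphericalMask <- function(dims, radius = NULL) {
    if (is.null(radius)) radius <- min(dims) / 2 - 1
    ctr <- (dims - 1) / 2
    x <- (0:(dims[1] - 1)) - ctr[1]
    y <- (0:(dims[2] - 1)) - ctr[2]
    z <- (0:(dims[3] - 1)) - ctr[3]
    r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
    r2 <= radius^2
}

.standardizeMasked <- function(vals) {
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    if (s == 0) stop("constant signal under the mask")
    (vals - m) / s
}

#' Precompute a standardized rotated-template bank
#'
#' Rotates the template over every grid rotation, applies the optional
#' missing-wedge filter, and standardizes each copy under the mask.  The
#' bank columns can then be scored against any number of subtomograms by
#' a single matrix product.
#'
#' @param template a [DensityVolume-class].
#' @param grid a [rotationGrid()].
#' @param mask logical array of the scoring mask; default centred sphere.
#' @param wedgeHalfangle wedge half-angle in degrees (90 = no wedge).
#' @return A `TemplateBank` list: `bank` (nMaskVoxels x nRotations),
#'   `mask`, `grid`, `wedgeHalfangle`.
#' @export
rotatedTemplateBank <- function(template, grid, mask = NULL,
                                wedgeHalfangle = 90) {
    d <- dim(template@data)
    if (is.null(mask)) mask <- .sphericalMask(d)
    if (!any(mask)) stop("empty mask")
    wedge <- if (wedgeHalfangle < 90) wedgeMask(d, wedgeHalfangle) else NULL
    nr <- dim(grid$rotations)[3]
    bank <- matrix(0, sum(mask), nr)
    for (k in seq_len(nr)) {
        v <- rotateVolume(template, grid$rotations[, , k])@data
        if (!is.null(wedge)) v <- .applyWedge(v, wedge)
        bank[, k] <- .standardizeMasked(v[mask])
    }
    structure(list(bank = bank, mask = mask, grid = grid,
                   wedgeHalfangle = wedgeHalfangle),
              class = "TemplateBank")
}

#' Constrained cross-correlation score of a subtomogram against a template
#'
#' For every grid rotation the template is rotated (trilinear), wedge
#' filtered with the same binary wedge as the subtomogram, and both are
#' standardized under the mask; the score is the masked normalized
#' cross-correlation at zero translational lag (subtomograms are assumed
#' particle-centred).  The best score over the grid is reported together
#' with its z-score against the per-rotation score population.
#'
#' @param subtomogram a [DensityVolume-class].
#' @param template a [DensityVolume-class] of the same shape (ignored
#'   when `bank` is supplied).
#' @param grid a [rotationGrid()] (ignored when `bank` is supplied).
#' @param mask logical array; default centred spherical mask.
#' @param wedgeHalfangle wedge half-angle in degrees.
#' @param bank optional precomputed [rotatedTemplateBank()].
#' @return A `ScoreResult` list: `bestScore`, `bestRotation` (3x3),
#'   `bestIndex`, `scores` (per rotation), `zscore`.
#' @export
cccScore <- function(subtomogram, template = NULL, grid = NULL,
                     mask = NULL, wedgeHalfangle = 90, bank = NULL) {
    if (is.null(bank)) {
        if (is.null(template) || is.null(grid))
            stop("either 'bank' or both 'template' and 'grid' required")
        if (!all(dim(subtomogram@data) == dim(template@data)))
            stop("subtomogram and template shapes differ")
        bank <- rotatedTemplateBank(template, grid, mask, wedgeHalfangle)
    }
    d <- dim(subtomogram@data)
    if (!all(dim(bank$mask) == d))
        stop("subtomogram shape does not match the template bank")
    v <- subtomogram@data
    if (bank$wedgeHalfangle < 90)
        v <- .applyWedge(v, wedgeMask(d, bank$wedgeHalfangle))
    s <- .standardizeMasked(v[bank$mask])
    scores <- drop(crossprod(bank$bank, s)) / length(s)
    best <- which.max(scores)
    structure(list(bestScore = scores[best],
                   bestRotation = bank$grid$rotations[, , best],
                   bestIndex = best, scores = scores,
                   zscore = peakZscore(scores, scores[best])),
              class = "ScoreResult")
}

#' Assign a subtomogram to the template with the higher CCC score
#'
#' @param scoreA,scoreB `ScoreResult` objects for the same subtomogram.
#' @return `"A"` or `"B"`; an exact tie yields `"A"` with a warning.
#' @export
assignClass <- function(scoreA, scoreB) {
    if (scoreA$bestScore == scoreB$bestScore)
        warning("exact CCC tie; assigning class A by convention")
    if (scoreA$bestScore >= scoreB$bestScore) "A" else "B"
}

#' Score and classify a set of subtomograms against two templates
#'
#' Builds one rotated-template bank per template and scores every
#' subtomogram against both; the class with the higher best CCC wins.
#'
#' @param subtomograms list of [DensityVolume-class].
#' @param templateA,templateB same-shape templates.
#' @param grid a [rotationGrid()].
#' @param mask optional logical mask array.
#' @param wedgeHalfangle wedge half-angle in degrees.
#' @return data.frame `subtomo_id score_a score_b label`; attribute
#'   `bestRotations` holds per-subtomogram winning-template rotations
#'   (3 x 3 x n).
#' @export
assignClasses <- function(subtomograms, templateA, templateB, grid,
                          mask = NULL, wedgeHalfangle = 90) {
    bankA <- rotatedTemplateBank(templateA, grid, mask, wedgeHalfangle)
    bankB <- rotatedTemplateBank(templateB, grid, bankA$mask,
                                 wedgeHalfangle)
    n <- length(subtomograms)
    sa <- sb <- numeric(n)
    lab <- character(n)
    rots <- array(0, c(3, 3, n))
    for (i in seq_len(n)) {
        ra <- cccScore(subtomograms[[i]], bank = bankA)
        rb <- cccScore(subtomograms[[i]], bank = bankB)
        sa[i] <- ra$bestScore; sb[i] <- rb$bestScore
        lab[i] <- assignClass(ra, rb)
        rots[, , i] <- if (lab[i] == "A") ra$bestRotation else
                       rb$bestRotation
    }
    out <- data.frame(subtomo_id = seq_len(n), score_a = sa,
                      score_b = sb, label = lab)
    attr(out, "bestRotations") <- rots
    out
}

#' Z-score of a candidate score against a score population
#'
#' @param scores numeric population (>= 2 values, nonzero spread).
#' @param candidate candidate score.
#' @return `(candidate - mean(scores)) / sd(scores)`.
#' @export
peakZscore <- function(scores, candidate) {
    if (length(scores) < 2) stop("need at least two scores")
    s <- stats::sd(scores)
    if (s == 0) stop("zero spread in the score population")
    (candidate - mean(scores)) / s
}

#' Threshold scored peaks at a minimum z-score
#'
#' @param results data.frame with a `zscore` column, or a list of
#'   `ScoreResult` objects.
#' @param zMin minimum z-score (default 18, the peak-cleaning threshold).
#' @return The surviving subset.
#' @export
thresholdPeaks <- function(results, zMin = 18) {
    if (is.data.frame(results)) {
        results[results$zscore >= zMin, , drop = FALSE]
    } else {
        Filter(function(r) r$zscore >= zMin, results)
    }
}
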