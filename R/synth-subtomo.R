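# Toy subtomogram generator: rotated copies of one of two templates,
# optional binary missing-wedge filtering, additive Gaussian noise.

#' Binary missing-wedge mask in the Fourier domain
#'
#' The tilt axis is y and the beam axis z: a frequency component is kept
#' when the angle of its (kx, kz) projection above the kx axis is at most
#' the wedge half-angle.  `halfangle = 90` keeps everything.
#'
#' @param dims integer(3) volume dimensions.
#' @param halfangle maximum tilt angle in degrees (0, 90].
#' @return A logical array of kept frequencies (fft layout).
#' @export
wedgeMask <- function(dims, halfangle) {
    stopifnot(halfangle > 0, halfangle <= 90)
    kx <- .fftfreq(dims[1])
    kz <- .fftfreq(dims[3])
    ang <- atan2(abs(rep(kz, each = dims[1])), abs(rep(kx, times = dims[3])))
    keep2d <- ang <= halfangle * pi / 180 + 1e-12
    aperm(array(rep(keep2d, times = dims[2]), c(dims[1], dims[3], dims[2])),
          c(1, 3, 2))
}

.applyWedge <- function(arr, wedge) {
    Re(stats::fft(stats::fft(arr) * wedge, inverse = TRUE)) / length(arr)
}

#' Rotate a volume about its centre
#'
#' Resamples the volume under rotation `R` (trilinear pull-back:
#' `out(p) = in(R^T (p - c) + c)`).  Samples falling outside the input
#' grid are set to `fill`.
#'
#' @param volume a [DensityVolume-class].
#' @param R 3x3 rotation matrix.
#' @param fill value for out-of-grid samples.
#' @return The rotated [DensityVolume-class].
#' @export
rotateVolume <- function(volume, R, fill = 0) {
    d <- dim(volume@data)
    ctr <- (d - 1) / 2
    g <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
    p <- sweep(g, 2, ctr)
    q <- p %*% R + matrix(ctr, nrow(p), 3, byrow = TRUE)  # p %*% R == t(R^T q)
    v <- trilinearInterp(volume@data, q, fill = fill)
    DensityVolume(array(v, dim = d), voxelSize = volume@voxelSize,
                  origin = volume@origin, label = volume@label)
}

#' Two distinguishable toy particle templates
#'
#' Builds a pair of blob-composite densities: template A (the larger,
#' "80S-like" particle) and the smaller template B ("60S-like") each
#' combine three unequal Gaussian blobs along different axes, so both
#' are fully asymmetric (no rotation maps either onto itself, which
#' keeps the best-scoring orientation well defined).  Both are
#' positive-contrast and centred.
#'
#' @param n cube edge length in voxels.
#' @param voxelSize voxel size in nm.
#' @return list with `templateA` and `templateB` ([DensityVolume-class]).
#' @export
makeToyTemplates <- function(n = 16, voxelSize = 1) {
    g <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1)))
    ctr <- (n - 1) / 2
    blob <- function(cen, r, amp) {
        d2 <- (g[, 1] - ctr - cen[1])^2 + (g[, 2] - ctr - cen[2])^2 +
              (g[, 3] - ctr - cen[3])^2
        amp * exp(-d2 / (2 * r^2))
    }
    s <- n / 16
    a <- blob(c(0, 0, 0), 3 * s, 1) + blob(c(3.5 * s, 0, 0), 2 * s, 0.9) +
         blob(c(0, 3 * s, 1.5 * s), 1.5 * s, 0.8)
    b <- blob(c(0, 0, 0), 3 * s, 1) +
         blob(c(-2.5 * s, -2 * s, 0), 1.8 * s, 0.7) +
         blob(c(0, 1.5 * s, -3 * s), 1.2 * s, 0.6)
    list(templateA = DensityVolume(array(a, c(n, n, n)), voxelSize,
                                   label = "template A"),
         templateB = DensityVolume(array(b, c(n, n, n)), voxelSize,
                                   label = "template B"))
}

#' Generate toy subtomograms from two templates
#'
#' Each subtomogram is a rotated copy of its true-class template,
#' optionally filtered by a binary missing-wedge mask, plus white
#' Gaussian noise.  Deterministic given the seed.
#'
#' @param templateA,templateB same-shape [DensityVolume-class] templates.
#' @param n number of subtomograms.
#' @param noiseSd Gaussian noise standard deviation.
#' @param wedgeHalfangle wedge half-angle in degrees; 90 disables the
#'   wedge step.
#' @param seed integer seed.
#' @param classes optional character vector of `"A"`/`"B"` true classes;
#'   default random 50/50.
#' @param rotations optional 3 x 3 x n array of true rotations; default
#'   uniform random.
#' @return list with `volumes` (list of [DensityVolume-class]), `classes`
#'   (character), `rotations` (3 x 3 x n array).
#' @export
makeSubtomograms <- function(templateA, templateB, n, noiseSd = 0,
                             wedgeHalfangle = 90, seed = 1,
                             classes = NULL, rotations = NULL) {
    if (!all(dim(templateA@data) == dim(templateB@data)))
        stop("templates must have the same shape")
    stopifnot(n >= 1)
    set.seed(deriveSeed(seed, "subtomos"))
    if (is.null(classes)) classes <- sample(c("A", "B"), n, replace = TRUE)
    stopifnot(length(classes) == n, all(classes %in% c("A", "B")))
    if (is.null(rotations)) rotations <- randomRotations(n)
    d <- dim(templateA@data)
    wedge <- if (wedgeHalfangle < 90) wedgeMask(d, wedgeHalfangle) else NULL
    vols <- vector("list", n)
    for (i in seq_len(n)) {
        tmpl <- if (classes[i] == "A") templateA else templateB
        v <- rotateVolume(tmpl, rotations[, , i])
        if (!is.null(wedge)) v@data <- .applyWedge(v@data, wedge)
        if (noiseSd > 0)
            v@data <- v@data + array(stats::rnorm(prod(d), sd = noiseSd), d)
        v@label <- sprintf("subtomo %d (%s)", i, classes[i])
        vols[[i]] <- v
    }
    list(volumes = vols, classes = classes, rotations = rotations)
}
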