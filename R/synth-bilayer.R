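# Synthetic bilayer scenes.  Density model: each leaflet is a negative
# Gaussian trough (cryo-ET contrast: leaflets darker than background),
#   I(x) = -A * g(d1; sigma) - A * g(d2; sigma) + noise,
# with d1, d2 the vertical distances to the two leaflet mid-planes.  A
# circular patch of reduced thickness and a Gaussian indentation ring of
# the mid-surface emulate the membrane geometry observed under
# membrane-bound particles.

#' Specification of a synthetic bilayer scene
#'
#' @param gridShape integer(3) grid size in voxels.
#' @param voxelSize voxel size in nm.
#' @param thickness leaflet-to-leaflet separation t in nm (> 0).
#' @param troughWidth Gaussian trough sigma in nm (> 0).
#' @param troughDepth trough amplitude A in intensity units.
#' @param patchRadius radius (nm) of a central circular patch of reduced
#'   thickness; 0 disables.
#' @param patchThinning thickness reduction delta-t inside the patch
#'   (nm, < thickness).
#' @param indentRingRadius radius (nm) of a Gaussian indentation ring of
#'   the mid-surface; 0 disables.
#' @param indentDepth indentation depth in nm.
#' @param indentRingWidth radial sigma of the ring profile in nm.
#' @param noiseSd Gaussian noise standard deviation (intensity units).
#' @param invertContrast if TRUE leaflets are bright maxima instead of
#'   dark minima.
#' @param seed integer seed.
#' @return A validated `BilayerSpec` list.
#' @export
bilayerSpec <- function(gridShape = c(64, 64, 48), voxelSize = 0.87,
                        thickness = 6, troughWidth = 1, troughDepth = 1,
                        patchRadius = 0, patchThinning = 0,
                        indentRingRadius = 0, indentDepth = 0,
                        indentRingWidth = 3, noiseSd = 0,
                        invertContrast = FALSE, seed = 1) {
    if (thickness <= 0) stop("'thickness' must be > 0")
    if (troughWidth <= 0) stop("'troughWidth' must be > 0")
    if (patchThinning >= thickness)
        stop("'patchThinning' must be smaller than 'thickness'")
    if (patchRadius < 0 || indentRingRadius < 0)
        stop("radii must be >= 0")
    structure(list(gridShape = as.integer(gridShape),
                   voxelSize = voxelSize, thickness = thickness,
                   troughWidth = troughWidth, troughDepth = troughDepth,
                   patchRadius = patchRadius, patchThinning = patchThinning,
                   indentRingRadius = indentRingRadius,
                   indentDepth = indentDepth,
                   indentRingWidth = indentRingWidth,
                   noiseSd = noiseSd, invertContrast = invertContrast,
                   seed = as.integer(seed)),
              class = "BilayerSpec")
}

# mid-surface height above grid-centre plane, closed form in (x, y) nm
.bilayerMidSurface <- function(spec, x, y, cx, cy, z0) {
    if (spec$indentRingRadius <= 0 || spec$indentDepth == 0)
        return(rep(z0, length(x)))
    r <- sqrt((x - cx)^2 + (y - cy)^2)
    z0 - spec$indentDepth *
        exp(-(r - spec$indentRingRadius)^2 / (2 * spec$indentRingWidth^2))
}

#' Generate a synthetic bilayer volume, segmentation mask and ground truth
#'
#' The returned mask covers voxels within the bilayer envelope
#' (`|z - mid| <= t/2 + sigma`, anti-aliased over one voxel).  Ground
#' truth reports, per (x, y) grid position, the true local thickness
#' (reduced by `patchThinning` inside the patch) and the true mean
#' curvature of the mid-surface (negative where indented, for an upward
#' normal).  The noiseless volume is identical across seeds; only the
#' noise field depends on the seed.
#'
#' @param spec a [bilayerSpec()].
#' @return list with `volume` ([DensityVolume-class]), `mask`
#'   ([SegmentationMask-class]), `truth` (data.frame `x y thickness
#'   meanCurvature inPatch`), and `spec`.
#' @export
makeBilayerScene <- function(spec) {
    stopifnot(inherits(spec, "BilayerSpec"))
    d <- spec$gridShape
    vs <- spec$voxelSize
    xs <- ((0:(d[1] - 1)) + 0.5) * vs
    ys <- ((0:(d[2] - 1)) + 0.5) * vs
    zs <- ((0:(d[3] - 1)) + 0.5) * vs
    cx <- mean(range(xs)); cy <- mean(range(ys)); z0 <- mean(range(zs))
    halfx <- (max(xs) - min(xs)) / 2
    if (spec$patchRadius > halfx - 2 * vs ||
        (spec$indentRingRadius > 0 &&
         spec$indentRingRadius + 2 * spec$indentRingWidth > halfx))
        stop("grid too small for the requested patch/ring geometry")
    zmarg <- spec$thickness / 2 + 3 * spec$troughWidth +
             abs(spec$indentDepth)
    if (zmarg > (max(zs) - min(zs)) / 2)
        stop("grid too small along z for the requested bilayer envelope")

    xy <- expand.grid(x = xs, y = ys)
    r <- sqrt((xy$x - cx)^2 + (xy$y - cy)^2)
    inPatch <- spec$patchRadius > 0 & r <= spec$patchRadius
    tloc <- spec$thickness - spec$patchThinning * inPatch
    zc <- .bilayerMidSurface(spec, xy$x, xy$y, cx, cy, z0)

    # 3D fields by broadcasting the 2D maps along z
    nxy <- nrow(xy)
    Z <- rep(zs, each = nxy)
    ZC <- rep(zc, times = d[3])
    TL <- rep(tloc, times = d[3])
    s2 <- 2 * spec$troughWidth^2
    dens <- -spec$troughDepth *
        (exp(-(Z - (ZC - TL / 2))^2 / s2) + exp(-(Z - (ZC + TL / 2))^2 / s2))
    if (spec$invertContrast) dens <- -dens
    if (spec$noiseSd > 0) {
        set.seed(deriveSeed(spec$seed, "bilayer-noise"))
        dens <- dens + stats::rnorm(length(dens), sd = spec$noiseSd)
    }
    vol <- DensityVolume(array(dens, dim = d), voxelSize = vs,
                         label = "synthetic bilayer")

    env <- TL / 2 + spec$troughWidth
    mval <- pmin(1, pmax(0, (env + vs / 2 - abs(Z - ZC)) / vs))
    mask <- SegmentationMask(array(mval, dim = d), voxelSize = vs,
                             label = "synthetic bilayer mask")

    # mean curvature of the mid-surface by finite differences of the
    # closed-form height function (sign: indentation negative, upward normal)
    h <- 1e-3
    f <- function(px, py) .bilayerMidSurface(spec, px, py, cx, cy, z0)
    f0 <- f(xy$x, xy$y)
    fx <- (f(xy$x + h, xy$y) - f(xy$x - h, xy$y)) / (2 * h)
    fy <- (f(xy$x, xy$y + h) - f(xy$x, xy$y - h)) / (2 * h)
    fxx <- (f(xy$x + h, xy$y) - 2 * f0 + f(xy$x - h, xy$y)) / h^2
    fyy <- (f(xy$x, xy$y + h) - 2 * f0 + f(xy$x, xy$y - h)) / h^2
    fxy <- (f(xy$x + h, xy$y + h) - f(xy$x + h, xy$y - h) -
            f(xy$x - h, xy$y + h) + f(xy$x - h, xy$y - h)) / (4 * h^2)
    Hgraph <- ((1 + fy^2) * fxx - 2 * fx * fy * fxy + (1 + fx^2) * fyy) /
              (2 * (1 + fx^2 + fy^2)^1.5)
    truth <- data.frame(x = xy$x, y = xy$y, midHeight = f0,
                        thickness = tloc, meanCurvature = -Hgraph,
                        inPatch = inPatch)
    list(volume = vol, mask = mask, truth = truth, spec = spec)
}
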