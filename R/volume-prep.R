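# Volume preprocessing: low-pass filtering, z-score normalization and
# Wiener-like deconvolution.  All filters are linear radial filters
# applied in the Fourier domain.

.fftfreq <- function(n) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    k / n
}

# |frequency| array in cycles/nm for a volume's grid
.freqMagnitude <- function(dims, voxelSize) {
    fx <- .fftfreq(dims[1]) / voxelSize
    fy <- .fftfreq(dims[2]) / voxelSize
    fz <- .fftfreq(dims[3]) / voxelSize
    f2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
    sqrt(f2)
}

.applyRadialFilter <- function(volume, H) {
    Fv <- stats::fft(volume@data)
    out <- Re(stats::fft(Fv * H, inverse = TRUE)) / length(Fv)
    DensityVolume(out, voxelSize = volume@voxelSize, origin = volume@origin,
                  label = volume@label)
}

#' Low-pass filter a volume to a target resolution
#'
#' Attenuates frequency content beyond `1/resolution` with a raised-cosine
#' edge centred on the cutoff.  The DC component is untouched, so the
#' volume mean is preserved.  `resolution = Inf` returns the input
#' unchanged.
#'
#' @param volume a [DensityVolume-class].
#' @param resolution target resolution in nm (e.g. 2 nm for 20 Angstrom);
#'   must be at least twice the voxel size (Nyquist).
#' @param edgeWidth full width of the raised-cosine edge in cycles/nm;
#'   defaults to 20\% of the cutoff frequency.
#' @return The filtered [DensityVolume-class].
#' @examples
#' v <- DensityVolume(array(rnorm(16^3), c(16, 16, 16)), voxelSize = 0.5)
#' lp <- lowpassFilter(v, resolution = 2)
#' abs(mean(voxelData(lp)) - mean(voxelData(v))) < 1e-9
#' @export
lowpassFilter <- function(volume, resolution, edgeWidth = NULL) {
    stopifnot(is(volume, "DensityVolume"))
    if (is.infinite(resolution)) return(volume)
    if (resolution < 2 * volume@voxelSize)
        stop(sprintf(
            "resolution %.3g nm is below Nyquist (%.3g nm) for %.3g nm voxels",
            resolution, 2 * volume@voxelSize, volume@voxelSize))
    fc <- 1 / resolution
    if (is.null(edgeWidth)) edgeWidth <- 0.2 * fc
    f <- .freqMagnitude(dim(volume@data), volume@voxelSize)
    lo <- fc - edgeWidth / 2
    hi <- fc + edgeWidth / 2
    H <- ifelse(f <= lo, 1,
         ifelse(f >= hi, 0, 0.5 * (1 + cos(pi * (f - lo) / edgeWidth))))
    .applyRadialFilter(volume, H)
}

#' Z-score normalize a volume
#'
#' Rescales intensities to mean 0 and standard deviation 1.
#'
#' @param volume a [DensityVolume-class] with nonzero intensity variance.
#' @return The normalized [DensityVolume-class].
#' @export
zscoreNormalize <- function(volume) {
    stopifnot(is(volume, "DensityVolume"))
    s <- stats::sd(volume@data)
    if (!is.finite(s) || s == 0)
        stop("cannot z-score normalize a constant volume (zero variance)")
    DensityVolume((volume@data - mean(volume@data)) / s,
                  voxelSize = volume@voxelSize, origin = volume@origin,
                  label = volume@label)
}

#' Wiener-like deconvolution of a volume
#'
#' Applies the radial frequency filter
#' `W(f) = C(f) / (C(f)^2 + 1/SSNR(f))` with a pure exponential
#' amplitude-decay contrast model `C(f) = exp(-decay * f)` and
#' `SSNR(f) = strength * exp(-f / falloff)`.  Large `strength` approaches
#' the inverse filter `1/C(f)`; `strength -> 0` suppresses everything.
#'
#' @param volume a [DensityVolume-class].
#' @param falloff SSNR falloff constant in cycles/nm (> 0).
#' @param strength SSNR amplitude (> 0).
#' @param decay contrast-decay constant in nm (>= 0); 0 gives `C = 1`.
#' @return The deconvolved [DensityVolume-class].
#' @export
wienerDeconvolve <- function(volume, falloff, strength, decay = 1) {
    stopifnot(is(volume, "DensityVolume"))
    if (falloff <= 0 || strength <= 0 || decay < 0)
        stop("'falloff' and 'strength' must be positive, 'decay' non-negative")
    f <- .freqMagnitude(dim(volume@data), volume@voxelSize)
    C <- exp(-decay * f)
    ssnr <- strength * exp(-f / falloff)
    W <- C / (C^2 + 1 / ssnr)
    .applyRadialFilter(volume, W)
}
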