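# Bilayer thickness from intensity profiles along the membrane normal.
# Leaflets appear as the two most prominent profile minima; the profile
# is centred on the maximum between them.  Two readouts: minima-to-minima
# distance and inflection-to-inflection distance.

#' Extract an intensity profile along a line through a volume
#'
#' Samples the volume by trilinear interpolation along
#' `point + t * direction`, `t` in `[-halfLength, halfLength]`, centred on
#' `point`.
#'
#' @param volume a [DensityVolume-class].
#' @param point world-frame centre of the profile (nm).
#' @param direction direction vector (normalized internally).
#' @param halfLength half the profile length in nm.
#' @param spacing sample spacing in nm; defaults to the voxel size.
#' @return An `IntensityProfile` list: `samples`, `positions` (nm along
#'   the axis, centred on 0), `spacing`, `axisOrigin`, `axisDirection`.
#' @export
extractProfile <- function(volume, point, direction, halfLength,
                           spacing = voxelSize(volume)) {
    stopifnot(is(volume, "DensityVolume"), halfLength > 0, spacing > 0)
    dir <- .unit(direction)
    m <- floor(halfLength / spacing)
    t <- (-m:m) * spacing
    pts <- outer(t, dir) + matrix(point, length(t), 3, byrow = TRUE)
    idx <- .worldToIndex(volume, pts)
    v <- trilinearInterp(volume@data, idx)
    if (anyNA(v)) {
        bad <- range(t[is.na(v)])
        stop(sprintf(
            "profile exits the volume: samples at t in [%.3g, %.3g] nm lie outside",
            bad[1], bad[2]))
    }
    structure(list(samples = v, positions = t, spacing = spacing,
                   axisOrigin = point, axisDirection = dir),
              class = "IntensityProfile")
}

# local extrema of a numeric vector; returns interior indices
.localMinima <- function(y) {
    n <- length(y)
    which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
}

.localMaxima <- function(y) .localMinima(-y)

# prominence of minima: depth below the lowest bounding "col" toward the
# nearest deeper minimum or signal edge (scipy-style, on the inverted signal)
.minProminences <- function(y, mins) {
    vapply(mins, function(i) {
        left <- y[seq_len(i)]
        deeper <- which(left < y[i])
        lbase <- if (length(deeper) > 0) max(left[(max(deeper)):i]) else
                 max(left)
        right <- y[i:length(y)]
        deeperR <- which(right < y[i])
        rbase <- if (length(deeperR) > 0) max(right[1:min(deeperR)]) else
                 max(right)
        min(lbase, rbase) - y[i]
    }, numeric(1))
}

# 3-point parabolic sub-sample refinement of an extremum at index i
.parabolicRefine <- function(y, i) {
    if (i <= 1 || i >= length(y)) return(as.numeric(i))
    den <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (abs(den) < 1e-15) return(as.numeric(i))
    i + 0.5 * (y[i - 1] - y[i + 1]) / den
}

#' Detect bilayer leaflet features on an intensity profile
#'
#' Finds the two most prominent local minima (the leaflets), the maximum
#' between them (profile centre), and per-minimum inflection points --
#' positions of maximum absolute intensity gradient between each minimum
#' and its adjacent maximum on the chosen side.  All positions are
#' refined to sub-sample precision by 3-point parabolic interpolation.
#'
#' @param profile an `IntensityProfile` (see [extractProfile()]).
#' @param minProminence minimum prominence (intensity units) for a
#'   minimum to count as a leaflet.
#' @param inflectionSide `"outer"` (default) uses the adjacent maximum on
#'   the side away from the bilayer centre, spanning the full bilayer;
#'   `"inner"` uses the central maximum.
#' @return A `BilayerProfileFeatures` list: `minimaPositions` (nm),
#'   `centerMaxPosition`, `inflectionPositions`, `thicknessMinima`,
#'   `thicknessInflection`, `inflectionSide`, `nMinimaCandidates`.
#' @export
detectBilayerFeatures <- function(profile, minProminence = 0,
                                  inflectionSide = c("outer", "inner")) {
    inflectionSide <- match.arg(inflectionSide)
    y <- profile$samples
    pos <- profile$positions
    if (length(y) < 9) stop("profile too short (need >= 9 samples)")
    mins <- .localMinima(y)
    if (length(mins) > 0) {
        prom <- .minProminences(y, mins)
        keep <- prom >= minProminence
        mins <- mins[keep]; prom <- prom[keep]
    }
    if (length(mins) < 2)
        stop("no bilayer: fewer than two minima above prominence ",
             minProminence)
    if (length(mins) > 2) {
        # keep the two most prominent; break ties toward the profile centre
        ctr <- (length(y) + 1) / 2
        ord <- order(-prom, abs(mins - ctr))
        mins <- sort(mins[ord[1:2]])
    } else mins <- sort(mins)
    i1 <- mins[1]; i2 <- mins[2]
    between <- y[i1:i2]
    if (which.max(between) %in% c(1L, length(between)))
        stop("degenerate profile: minima are not separated by a maximum")
    iMax <- i1 - 1L + which.max(between)
    # gradient by central differences
    g <- c(NA, (y[-(1:2)] - y[1:(length(y) - 2)]) / (2 * profile$spacing), NA)
    inflectionAt <- function(iMin, iAdjMax) {
        lo <- min(iMin, iAdjMax); hi <- max(iMin, iAdjMax)
        if (hi - lo < 2) return(mean(pos[c(iMin, iAdjMax)]))
        seg <- (lo + 1):(hi - 1)
        ga <- abs(g[seg])
        j <- seg[which.max(ga)]
        jr <- .parabolicRefine(-abs(g), j)
        pos[1] + (jr - 1) * profile$spacing
    }
    adjacentMax <- function(iMin, side) {
        if (side == "inner") return(iMax)
        if (iMin < iMax) {   # left minimum: outer side is toward index 1
            mx <- .localMaxima(y[1:iMin])
            if (length(mx) > 0) max(mx) else 1L
        } else {
            mx <- .localMaxima(y[iMin:length(y)]) + iMin - 1L
            if (length(mx) > 0) min(mx) else length(y)
        }
    }
    refPos <- function(i) pos[1] + (.parabolicRefine(y, i) - 1) * profile$spacing
    m1 <- refPos(i1); m2 <- refPos(i2)
    f1 <- inflectionAt(i1, adjacentMax(i1, inflectionSide))
    f2 <- inflectionAt(i2, adjacentMax(i2, inflectionSide))
    structure(list(
        minimaPositions = c(m1, m2),
        centerMaxPosition = refPos(iMax),
        inflectionPositions = c(f1, f2),
        thicknessMinima = abs(m2 - m1),
        thicknessInflection = abs(f2 - f1),
        inflectionSide = inflectionSide,
        nMinimaCandidates = length(.localMinima(y))),
        class = "BilayerProfileFeatures")
}

#' Measure bilayer thickness for groups of profile sites
#'
#' Extracts a profile at each site, detects leaflet features and collects
#' one thickness per successfully measured site.  Failed sites (no
#' bilayer found, profile exiting the volume) are excluded and counted.
#'
#' @param volume a [DensityVolume-class].
#' @param sites data.frame with columns `x y z dx dy dz group`
#'   (world-nm points and direction vectors).
#' @param halfLength profile half-length in nm.
#' @param basis `"minima"` or `"inflection"` thickness readout.
#' @param minProminence passed to [detectBilayerFeatures()].
#' @param inflectionSide passed to [detectBilayerFeatures()].
#' @param spacing profile sample spacing (nm); default voxel size.
#' @return A `GroupMeasurements` data.frame with columns `site`, `group`,
#'   `basis`, `thickness`; attribute `nFailed` gives per-group failure
#'   counts.
#' @export
measureGroupThickness <- function(volume, sites, halfLength,
                                  basis = c("inflection", "minima"),
                                  minProminence = 0,
                                  inflectionSide = "outer",
                                  spacing = voxelSize(volume)) {
    basis <- match.arg(basis)
    stopifnot(all(c("x", "y", "z", "dx", "dy", "dz", "group") %in%
                  names(sites)))
    res <- lapply(seq_len(nrow(sites)), function(i) {
        tryCatch({
            pr <- extractProfile(volume,
                                 c(sites$x[i], sites$y[i], sites$z[i]),
                                 c(sites$dx[i], sites$dy[i], sites$dz[i]),
                                 halfLength, spacing = spacing)
            ft <- detectBilayerFeatures(pr, minProminence = minProminence,
                                        inflectionSide = inflectionSide)
            if (basis == "minima") ft$thicknessMinima else
                ft$thicknessInflection
        }, error = function(e) NA_real_)
    })
    th <- unlist(res)
    ok <- !is.na(th)
    nFailed <- tapply(!ok, sites$group, sum)
    for (gname in unique(sites$group))
        if (!any(ok & sites$group == gname))
            stop("group '", gname, "' has no successful measurements")
    out <- data.frame(site = which(ok), group = sites$group[ok],
                      basis = basis, thickness = th[ok])
    attr(out, "nFailed") <- nFailed
    class(out) <- c("GroupMeasurements", "data.frame")
    out
}
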