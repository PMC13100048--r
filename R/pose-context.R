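# Ribosome-vault spatial and orientational context: nearest-neighbour
# pairing under a centre-distance rule, relative orientations, spherical
# histograms, RTC-like classification and the contingency summaries.

#' Pair each ribosome with its nearest vault under a distance cutoff
#'
#' Pairing is per tomogram (identifiers must agree) and directional: a
#' ribosome is assigned to its nearest vault if and only if the centre
#' distance is at most `cutoff` (inclusive).  Equidistant vaults are
#' broken toward the lower vault index.  The relative rotation is
#' `R_rel = t(R_vault) %*% R_ribosome` (ribosome pose expressed in the
#' vault frame).
#'
#' @param ribosomes,vaults [PoseSet-class] objects in the same world
#'   frame.
#' @param cutoff pairing distance in nm (default 10, the encapsulation
#'   rule).
#' @return A `PairAssignment` data.frame: `ribosomeIndex`, `vaultIndex`,
#'   `distance`; attribute `relativeRotations` holds the 3 x 3 x npair
#'   array.
#' @export
pairNearest <- function(ribosomes, vaults, cutoff = 10) {
    stopifnot(cutoff > 0)
    if (length(vaults) == 0 || length(ribosomes) == 0)
        return(structure(data.frame(ribosomeIndex = integer(0),
                                    vaultIndex = integer(0),
                                    distance = numeric(0)),
                         relativeRotations = array(0, c(3, 3, 0)),
                         class = c("PairAssignment", "data.frame")))
    ri <- integer(0); vi <- integer(0); dd <- numeric(0)
    vpos <- positions(vaults)
    rpos <- positions(ribosomes)
    for (i in seq_len(length(ribosomes))) {
        sameTomo <- which(tomogramId(vaults) == tomogramId(ribosomes)[i])
        if (length(sameTomo) == 0) next
        d <- sqrt(colSums((t(vpos[sameTomo, , drop = FALSE]) - rpos[i, ])^2))
        j <- sameTomo[which.min(d)]     # which.min takes the first = lowest index
        dm <- min(d)
        if (dm <= cutoff) {
            ri <- c(ri, i); vi <- c(vi, j); dd <- c(dd, dm)
        }
    }
    rel <- array(0, c(3, 3, length(ri)))
    for (k in seq_along(ri))
        rel[, , k] <- t(rotations(vaults)[, , vi[k]]) %*%
                      rotations(ribosomes)[, , ri[k]]
    structure(data.frame(ribosomeIndex = ri, vaultIndex = vi,
                         distance = dd),
              relativeRotations = rel,
              class = c("PairAssignment", "data.frame"))
}

#' Relative reference axes of paired particles
#'
#' Applies each pair's relative rotation to the ribosome reference axis,
#' yielding that axis expressed in the vault frame.  Invariant under a
#' common global rotation of both pose sets.
#'
#' @param pairs a `PairAssignment` (see [pairNearest()]).
#' @param referenceAxis unit 3-vector in the ribosome frame.
#' @return npair x 3 matrix of unit vectors.
#' @export
relativeAxis <- function(pairs, referenceAxis = c(0, 0, 1)) {
    ref <- .unit(referenceAxis)
    rel <- attr(pairs, "relativeRotations")
    out <- matrix(0, nrow(pairs), 3)
    for (k in seq_len(nrow(pairs)))
        out[k, ] <- rel[, , k] %*% ref
    out
}

#' Spherical histogram over subdivided-icosahedron bins
#'
#' Bins are the spherical Voronoi cells of the face centroids of an
#' icosahedron subdivided `nSubdiv` times: a near-equal-area partition
#' of the sphere.  Each axis is counted in the bin whose centroid is
#' nearest (maximum dot product).
#'
#' @param axes n x 3 matrix of direction vectors (normalized internally).
#' @param nSubdiv icosahedron subdivision level (>= 0); bin count is
#'   `20 * 4^nSubdiv`.
#' @return A `SphericalHistogram` list: `binDirections` (bins x 3),
#'   `counts`, `total`.
#' @export
sphericalHistogram <- function(axes, nSubdiv = 1) {
    stopifnot(nSubdiv >= 0)
    ico <- .icosahedron()
    for (s in seq_len(nSubdiv)) ico <- .subdivideSphere(ico$v, ico$f)
    ctr <- .rowUnit((ico$v[ico$f[, 1], ] + ico$v[ico$f[, 2], ] +
                     ico$v[ico$f[, 3], ]) / 3)
    axes <- matrix(axes, ncol = 3)
    counts <- rep(0L, nrow(ctr))
    if (nrow(axes) > 0) {
        nn <- sqrt(rowSums(axes^2))
        if (any(nn < 1e-12)) stop("zero-length direction vector")
        u <- axes / nn
        bin <- max.col(u %*% t(ctr), ties.method = "first")
        tab <- table(bin)
        counts[as.integer(names(tab))] <- as.integer(tab)
    }
    structure(list(binDirections = ctr, counts = counts,
                   total = nrow(axes)),
              class = "SphericalHistogram")
}

#' Classify paired ribosomes as RTC-like by relative-axis alignment
#'
#' A pair is RTC-like when the angle between its relative axis (ribosome
#' reference axis in the vault frame) and `targetAxis` is at most
#' `thetaRtc` degrees (inclusive boundary).
#'
#' @param pairs a `PairAssignment`.
#' @param referenceAxis ribosome reference axis.
#' @param targetAxis target direction in the vault frame.
#' @param thetaRtc angular threshold in degrees (0 < thetaRtc < 90).
#' @return factor of `"RTC-like"` / `"other"` per pair.
#' @export
classifyRTC <- function(pairs, referenceAxis = c(0, 0, 1),
                        targetAxis = c(0, 0, 1), thetaRtc = 30) {
    stopifnot(thetaRtc > 0, thetaRtc < 90)
    ax <- relativeAxis(pairs, referenceAxis)
    tgt <- .unit(targetAxis)
    ang <- acos(pmax(-1, pmin(1, ax %*% tgt))) * 180 / pi
    factor(ifelse(ang <= thetaRtc, "RTC-like", "other"),
           levels = c("RTC-like", "other"))
}

#' Contingency test of RTC-like orientation between particle sets
#'
#' Builds the 2x2 table (rows: membrane / cytosolic sets; columns:
#' RTC-like / other) and applies the two-sided Fisher exact test.
#'
#' @param labelsMembrane,labelsCytosolic factors from [classifyRTC()] or
#'   logical vectors (TRUE = RTC-like); each non-empty.
#' @return list with `table` (2x2 matrix) and `test` (`TestResult`).
#' @export
orientationContingency <- function(labelsMembrane, labelsCytosolic) {
    toCount <- function(l) {
        if (is.factor(l)) l <- l == "RTC-like"
        c(sum(l), sum(!l))
    }
    if (length(labelsMembrane) == 0 || length(labelsCytosolic) == 0)
        stop("both label sets must be non-empty")
    m <- toCount(labelsMembrane); cc <- toCount(labelsCytosolic)
    tab <- contingency2x2(m[1], m[2], cc[1], cc[2])
    dimnames(tab) <- list(set = c("membrane", "cytosolic"),
                          orientation = c("RTC-like", "other"))
    list(table = tab, test = fisherExactTwoSided(tab))
}

#' Encapsulation summary per vault class
#'
#' Counts vaults with and without an encapsulated (paired) ribosome per
#' class, reports percentages (nearest integer per class, one decimal
#' for the overall fraction) and the two-sided Fisher exact test on the
#' 2x2 table.
#'
#' @param vaultClasses character/factor of `"cytosolic"`/`"membrane"`
#'   per vault.
#' @param pairs a `PairAssignment` from [pairNearest()].
#' @return list with `summary` (data.frame per class: `n`,
#'   `encapsulated`, `percent`), `overallPercent`, `table`, `test`.
#' @export
encapsulationSummary <- function(vaultClasses, pairs) {
    if (anyNA(vaultClasses)) stop("every vault must be classified")
    vaultClasses <- as.character(vaultClasses)
    enc <- seq_along(vaultClasses) %in% pairs$vaultIndex
    cls <- sort(unique(vaultClasses))
    n <- vapply(cls, function(cl) sum(vaultClasses == cl), numeric(1))
    e <- vapply(cls, function(cl) sum(enc[vaultClasses == cl]), numeric(1))
    summary <- data.frame(class = cls, n = n, encapsulated = e,
                          percent = round(100 * e / n))
    if (length(cls) != 2)
        stop("expected exactly two vault classes, got ", length(cls))
    if (any(n == 0)) stop("empty vault class")
    tab <- contingency2x2(e[1], n[1] - e[1], e[2], n[2] - e[2])
    dimnames(tab) <- list(class = cls,
                          outcome = c("encapsulated", "empty"))
    list(summary = summary,
         overallPercent = round(100 * sum(e) / sum(n), 1),
         table = tab, test = fisherExactTwoSided(tab))
}

#' Class-fraction summary of a vault population
#'
#' Per-class count and percentage of the total, one-decimal rounding.
#'
#' @param vaultClasses character/factor of class labels per vault.
#' @return data.frame with `class`, `n`, `percent`.
#' @export
classFractionSummary <- function(vaultClasses) {
    if (length(vaultClasses) == 0) stop("at least one vault required")
    vaultClasses <- as.character(vaultClasses)
    cls <- sort(unique(vaultClasses))
    n <- vapply(cls, function(cl) sum(vaultClasses == cl), numeric(1))
    data.frame(class = cls, n = n,
               percent = round(100 * n / length(vaultClasses), 1))
}
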