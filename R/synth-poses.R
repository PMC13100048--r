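# Synthetic vault/ribosome pose populations.  A controllable fraction of
# vaults encapsulates a ribosome placed inside the pairing rule's radius;
# the relative ribosome orientation is drawn either uniformly over
# rotations or with its reference axis from a von Mises-Fisher
# distribution about a target axis.

#' Specification of a synthetic vault/ribosome pose population
#'
#' @param nVaultsCytosolic,nVaultsMembrane vault counts per class.
#' @param encapsulationFraction fraction of vaults per class holding a
#'   ribosome; a single value is recycled, or a named vector
#'   `c(cytosolic = ..., membrane = ...)`.
#' @param relativeOrientationMode `"concentrated"` or `"uniform"`.
#' @param kappa von Mises-Fisher concentration (> 0, concentrated mode).
#' @param referenceAxis ribosome reference axis (particle frame).
#' @param targetAxis target direction, in the vault frame, about which
#'   concentrated relative axes cluster.
#' @param boxExtent cubic box edge length in nm.
#' @param minSeparation minimum vault-vault centre distance in nm.
#' @param encapsulationRadius maximum ribosome offset from its vault
#'   centre (nm); must stay inside the downstream pairing cutoff.
#' @param nFreeRibosomes additional non-encapsulated ribosomes placed at
#'   least two pairing cutoffs away from every vault.
#' @param pairingCutoff the pairing rule distance the geometry must
#'   respect (nm).
#' @param thetaRtc angular bin half-width (degrees) used for the
#'   ground-truth RTC-like labels.
#' @param seed integer seed.
#' @return A validated `PopulationSpec` list.
#' @export
populationSpec <- function(nVaultsCytosolic = 50, nVaultsMembrane = 0,
                           encapsulationFraction = 0.1,
                           relativeOrientationMode = c("concentrated",
                                                       "uniform"),
                           kappa = 100, referenceAxis = c(0, 0, 1),
                           targetAxis = c(0, 0, 1), boxExtent = 500,
                           minSeparation = 40, encapsulationRadius = 8,
                           nFreeRibosomes = 25, pairingCutoff = 10,
                           thetaRtc = 30, seed = 1) {
    relativeOrientationMode <- match.arg(relativeOrientationMode)
    if (nVaultsCytosolic < 0 || nVaultsMembrane < 0 || nFreeRibosomes < 0)
        stop("counts must be >= 0")
    ef <- encapsulationFraction
    if (length(ef) == 1) ef <- c(cytosolic = ef, membrane = ef)
    if (any(ef < 0 | ef > 1))
        stop("'encapsulationFraction' must lie in [0, 1]")
    if (relativeOrientationMode == "concentrated" && kappa <= 0)
        stop("'kappa' must be > 0 in concentrated mode")
    if (encapsulationRadius >= pairingCutoff)
        stop("'encapsulationRadius' must be below 'pairingCutoff'")
    structure(list(nVaultsCytosolic = as.integer(nVaultsCytosolic),
                   nVaultsMembrane = as.integer(nVaultsMembrane),
                   encapsulationFraction = ef,
                   relativeOrientationMode = relativeOrientationMode,
                   kappa = kappa, referenceAxis = .unit(referenceAxis),
                   targetAxis = .unit(targetAxis),
                   boxExtent = boxExtent, minSeparation = minSeparation,
                   encapsulationRadius = encapsulationRadius,
                   nFreeRibosomes = as.integer(nFreeRibosomes),
                   pairingCutoff = pairingCutoff, thetaRtc = thetaRtc,
                   seed = as.integer(seed)),
              class = "PopulationSpec")
}

# Poisson-disc style placement by rejection; bounded retries
.placePoints <- function(n, extent, minSep, maxTries = 2000L) {
    pts <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(pts) < n) {
        cand <- stats::runif(3, 0, extent)
        ok <- nrow(pts) == 0 ||
              min(sqrt(colSums((t(pts) - cand)^2))) >= minSep
        if (ok) pts <- rbind(pts, cand)
        tries <- tries + 1L
        if (tries > maxTries * n)
            stop("packing error: box too small for ", n,
                 " points with minimum separation ", minSep, " nm")
    }
    pts
}

# rotation whose reference-axis image is `axis`, with uniform spin
.rotationWithAxisImage <- function(referenceAxis, axis) {
    rotationFromTo(referenceAxis, axis) %*%
        axisAngleMatrix(referenceAxis, stats::runif(1, 0, 360))
}

#' Generate a synthetic vault/ribosome pose population
#'
#' Vault centres are placed with a minimum separation in a cubic box;
#' exactly `floor(fraction * n)` vaults per class receive an encapsulated
#' ribosome, whose centre is offset uniformly within
#' `encapsulationRadius` of the vault centre (inside the pairing rule)
#' and whose orientation realizes the requested relative-axis
#' distribution.  Free ribosomes are placed at least two pairing cutoffs
#' from every vault.
#'
#' @param spec a [populationSpec()].
#' @return list with `vaults` and `ribosomes` ([PoseSet-class]; vault
#'   class labels `"cytosolic"`/`"membrane"`), and `truth`: a data.frame
#'   per ribosome with `vaultIndex` (NA for free ribosomes),
#'   `encapsulated`, `rtcLike`, `relativeAngle` (degrees to the target
#'   axis).
#' @export
makePosePopulation <- function(spec) {
    stopifnot(inherits(spec, "PopulationSpec"))
    set.seed(deriveSeed(spec$seed, "poses"))
    nV <- spec$nVaultsCytosolic + spec$nVaultsMembrane
    if (nV == 0) stop("population must contain at least one vault")
    vpos <- .placePoints(nV, spec$boxExtent, spec$minSeparation)
    vclass <- rep(c("cytosolic", "membrane"),
                  c(spec$nVaultsCytosolic, spec$nVaultsMembrane))
    vrot <- randomRotations(nV)
    vaults <- PoseSet(vpos, vrot, classLabel = vclass)

    encIdx <- integer(0)
    for (cl in c("cytosolic", "membrane")) {
        idx <- which(vclass == cl)
        k <- floor(spec$encapsulationFraction[[cl]] * length(idx))
        if (k > 0) encIdx <- c(encIdx, sample(idx, k))
    }
    encIdx <- sort(encIdx)
    nEnc <- length(encIdx)

    rpos <- matrix(0, 0, 3); rrotL <- list()
    relAngle <- numeric(0)
    for (i in encIdx) {
        u <- stats::runif(1)^(1 / 3) * spec$encapsulationRadius
        dir <- .unit(stats::rnorm(3))
        rpos <- rbind(rpos, vpos[i, ] + u * dir)
        if (spec$relativeOrientationMode == "concentrated") {
            ax <- drop(sampleVonMisesFisher(1, spec$targetAxis, spec$kappa))
            Rrel <- .rotationWithAxisImage(spec$referenceAxis, ax)
        } else {
            Rrel <- randomRotations(1)[, , 1]
            ax <- drop(Rrel %*% spec$referenceAxis)
        }
        rrotL[[length(rrotL) + 1]] <- vrot[, , i] %*% Rrel
        relAngle <- c(relAngle,
                      acos(max(-1, min(1, sum(ax * spec$targetAxis)))) *
                      180 / pi)
    }

    if (spec$nFreeRibosomes > 0) {
        placed <- 0L; tries <- 0L
        while (placed < spec$nFreeRibosomes) {
            cand <- stats::runif(3, 0, spec$boxExtent)
            if (min(sqrt(colSums((t(vpos) - cand)^2))) >=
                2 * spec$pairingCutoff) {
                rpos <- rbind(rpos, cand)
                rrotL[[length(rrotL) + 1]] <- randomRotations(1)[, , 1]
                placed <- placed + 1L
            }
            tries <- tries + 1L
            if (tries > 2000L * spec$nFreeRibosomes)
                stop("packing error: cannot place free ribosomes")
        }
    }
    nR <- nrow(rpos)
    rrot <- array(unlist(rrotL), c(3, 3, nR))
    ribosomes <- PoseSet(rpos, rrot, classLabel = rep("ribosome", nR))
    truth <- data.frame(
        vaultIndex = c(encIdx, rep(NA_integer_, nR - nEnc)),
        encapsulated = c(rep(TRUE, nEnc), rep(FALSE, nR - nEnc)),
        relativeAngle = c(relAngle, rep(NA_real_, nR - nEnc)))
    truth$rtcLike <- !is.na(truth$relativeAngle) &
                     truth$relativeAngle <= spec$thetaRtc
    list(vaults = vaults, ribosomes = ribosomes, truth = truth, spec = spec)
}
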