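# Shared numerical helpers: seeded RNG streams, rotation algebra,
# trilinear interpolation, directional sampling.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Each generator draws from its own stream, derived from the master seed
#' by a fixed label, so adding one generator call does not shift the
#' random numbers of another.
#'
#' @param seed integer master seed.
#' @param label character stream label.
#' @return An integer seed below 2^31.
#' @export
deriveSeed <- function(seed, label) {
    h <- as.double(seed %% 2147483629)
    for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483629
    as.integer(h)
}

.unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("cannot normalize a zero-length vector")
    v / n
}

.rowUnit <- function(m) {
    n <- sqrt(rowSums(m^2))
    m / n
}

#' Elementary and Euler rotations
#'
#' `rotX`, `rotY`, `rotZ` build elementary rotation matrices (right-handed,
#' counter-clockwise looking down the axis).  `eulerToMatrix` composes an
#' intrinsic ZXZ triple (degrees) into a rotation matrix
#' `R = Rz(phi) %*% Rx(theta) %*% Rz(psi)`; `matrixToEuler` inverts it.
#'
#' @param deg angle in degrees.
#' @return 3x3 rotation matrix (or numeric(3) of angles for the inverse).
#' @name rotations-euler
NULL

#' @rdname rotations-euler
#' @export
rotX <- function(deg) {
    a <- deg * pi / 180
    matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rotations-euler
#' @export
rotY <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rotations-euler
#' @export
rotZ <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rotations-euler
#' @param phi,theta,psi intrinsic ZXZ Euler angles in degrees.
#' @param convention Euler convention tag; only `"zxz"` (intrinsic) is
#'   implemented.
#' @export
eulerToMatrix <- function(phi, theta, psi, convention = "zxz") {
    if (tolower(convention) != "zxz")
        stop("unknown Euler convention '", convention,
             "'; supported: 'zxz' (intrinsic)")
    rotZ(phi) %*% rotX(theta) %*% rotZ(psi)
}

#' @rdname rotations-euler
#' @param R 3x3 rotation matrix.
#' @export
matrixToEuler <- function(R, convention = "zxz") {
    if (tolower(convention) != "zxz")
        stop("unknown Euler convention '", convention, "'")
    ct <- max(-1, min(1, R[3, 3]))
    theta <- acos(ct)
    if (sin(theta) > 1e-9) {
        phi <- atan2(R[1, 3], -R[2, 3])
        psi <- atan2(R[3, 1], R[3, 2])
    } else {
        # gimbal: R is a pure z-rotation by phi + sign(ct) * psi
        psi <- 0
        phi <- atan2(R[2, 1], R[1, 1])
        if (ct < 0) phi <- -phi
    }
    c(phi = phi, theta = theta, psi = psi) * 180 / pi
}

#' Rotation utilities
#'
#' `randomRotations` draws uniform rotations (quaternion method);
#' `rotationFromTo` builds the minimal rotation mapping one unit vector to
#' another; `rotationAngle` returns the rotation angle of a matrix in
#' degrees; `axisAngleMatrix` builds a rotation about an axis.
#'
#' @param n number of rotations.
#' @param seed optional integer seed (uses the current RNG state if NULL).
#' @return `randomRotations`: a 3 x 3 x n array.
#' @name rotation-utils
NULL

#' @rdname rotation-utils
#' @export
randomRotations <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    q <- matrix(stats::rnorm(4 * n), n, 4)
    q <- q / sqrt(rowSums(q^2))
    out <- array(0, c(3, 3, n))
    for (i in seq_len(n)) out[, , i] <- .quatToMatrix(q[i, ])
    out
}

.quatToMatrix <- function(q) {
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
        1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
        3, 3)
}

#' @rdname rotation-utils
#' @param a,b unit 3-vectors.
#' @export
rotationFromTo <- function(a, b) {
    a <- .unit(a); b <- .unit(b)
    v <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    c0 <- sum(a * b)
    s <- sqrt(sum(v^2))
    if (s < 1e-12) {
        if (c0 > 0) return(diag(3))
        # antiparallel: rotate 180 degrees about any axis orthogonal to a
        p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        ax <- .unit(p - sum(p * a) * a)
        return(axisAngleMatrix(ax, 180))
    }
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
}

#' @rdname rotation-utils
#' @param axis unit 3-vector rotation axis.
#' @param deg rotation angle in degrees.
#' @export
axisAngleMatrix <- function(axis, deg) {
    u <- .unit(axis)
    a <- deg * pi / 180
    ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(a) * ux + (1 - cos(a)) * ux %*% ux
}

#' @rdname rotation-utils
#' @param R 3x3 rotation matrix.
#' @export
rotationAngle <- function(R) {
    acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Trilinear interpolation in a 3D array
#'
#' Samples `arr` at fractional 0-based voxel-index coordinates.  Exact
#' integer coordinates reproduce the raw voxel values.
#'
#' @param arr 3D numeric array.
#' @param idx n x 3 matrix of fractional 0-based indices.
#' @param fill value for samples outside `[0, dim - 1]`; `NA` marks them.
#' @return numeric(n) of interpolated values.
#' @export
trilinearInterp <- function(arr, idx, fill = NA_real_) {
    d <- dim(arr)
    idx <- matrix(idx, ncol = 3)
    inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
              idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
              idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    out <- rep(fill, nrow(idx))
    if (!any(inside)) return(out)
    p <- idx[inside, , drop = FALSE]
    i0 <- floor(p)
    f <- p - i0
    i1 <- pmin(i0 + 1, matrix(rep(d - 1, each = nrow(i0)), ncol = 3))
    lin <- function(ix, iy, iz) arr[1 + ix + d[1] * (iy + d[2] * iz)]
    fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
    v <- lin(i0[, 1], i0[, 2], i0[, 3]) * (1 - fx) * (1 - fy) * (1 - fz) +
         lin(i1[, 1], i0[, 2], i0[, 3]) * fx       * (1 - fy) * (1 - fz) +
         lin(i0[, 1], i1[, 2], i0[, 3]) * (1 - fx) * fy       * (1 - fz) +
         lin(i1[, 1], i1[, 2], i0[, 3]) * fx       * fy       * (1 - fz) +
         lin(i0[, 1], i0[, 2], i1[, 3]) * (1 - fx) * (1 - fy) * fz +
         lin(i1[, 1], i0[, 2], i1[, 3]) * fx       * (1 - fy) * fz +
         lin(i0[, 1], i1[, 2], i1[, 3]) * (1 - fx) * fy       * fz +
         lin(i1[, 1], i1[, 2], i1[, 3]) * fx       * fy       * fz
    out[inside] <- v
    out
}

#' Sample directions from a von Mises-Fisher distribution on the sphere
#'
#' @param n number of samples.
#' @param mu unit mean direction.
#' @param kappa concentration parameter (> 0).
#' @return n x 3 matrix of unit vectors.
#' @export
sampleVonMisesFisher <- function(n, mu, kappa) {
    stopifnot(kappa > 0)
    mu <- .unit(mu)
    u <- stats::runif(n)
    # inverse-CDF sampling of the cosine to the mean direction
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
    phi <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - w^2))
    # orthonormal basis completing mu
    e1 <- if (abs(mu[1]) < 0.9) .unit(c(1, 0, 0) - mu[1] * mu) else
          .unit(c(0, 1, 0) - mu[2] * mu)
    e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
            mu[3] * e1[1] - mu[1] * e1[3],
            mu[1] * e1[2] - mu[2] * e1[1])
    outer(r * cos(phi), e1) + outer(r * sin(phi), e2) + outer(w, mu)
}

#' Near-uniform directions on the sphere (spherical Fibonacci lattice)
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacciSphere <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    g <- pi * (3 - sqrt(5))
    cbind(r * cos(g * i), r * sin(g * i), z)
}

.worldToIndex <- function(volume, pts) {
    sweep(matrix(pts, ncol = 3), 2, volume@origin) / volume@voxelSize - 0.5
}

.indexToWorld <- function(volume, idx) {
    sweep((matrix(idx, ncol = 3) + 0.5) * volume@voxelSize, 2,
          volume@origin, "+")
}
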