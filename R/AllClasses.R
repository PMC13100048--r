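#' @import methods
NULL

#' DensityVolume: a 3D intensity grid with physical voxel size
#'
#' Container for tomogram, subtomogram or subtomogram-average densities.
#' Values are in arbitrary intensity units; the voxel size is isotropic and
#' given in nanometres.  The world-frame position of the centre of voxel
#' `(i, j, k)` (0-based indices) is `origin + (c(i, j, k) + 0.5) * voxelSize`,
#' i.e. voxel centres sit half a voxel inside the volume boundary.
#'
#' @slot data numeric 3D array of intensities.
#' @slot voxelSize numeric(1), isotropic voxel edge length in nm.
#' @slot origin numeric(3), world position (nm) of the corner of voxel
#'   (0,0,0).
#' @slot label free-text description.
#' @exportClass DensityVolume
setClass("DensityVolume",
    representation(data = "array", voxelSize = "numeric",
                   origin = "numeric", label = "character"),
    prototype(voxelSize = 1, origin = c(0, 0, 0), label = ""))

setValidity("DensityVolume", function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "'data' must be a 3D array")
    if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
        object@voxelSize <= 0)
        msg <- c(msg, "'voxelSize' must be a single positive number")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "'origin' must be a finite numeric(3)")
    if (any(!is.finite(object@data)))
        msg <- c(msg, "'data' contains non-finite values")
    if (is.null(msg)) TRUE else msg
})

#' Construct a DensityVolume
#'
#' @param data numeric 3D array.
#' @param voxelSize voxel edge length in nm (isotropic).
#' @param origin world position (nm) of the corner of voxel (0,0,0).
#' @param label free-text label.
#' @return A [DensityVolume-class] object.
#' @examples
#' v <- DensityVolume(array(rnorm(8^3), dim = c(8, 8, 8)), voxelSize = 0.87)
#' voxelSize(v)
#' @export
DensityVolume <- function(data, voxelSize = 1, origin = c(0, 0, 0),
                          label = "") {
    new("DensityVolume", data = data, voxelSize = as.numeric(voxelSize),
        origin = as.numeric(origin), label = label)
}

#' SegmentationMask: a binary or probability membrane segmentation
#'
#' A [DensityVolume-class] whose values are restricted to `[0, 1]`.
#' Shares the half-voxel world-frame convention of its parent class.
#'
#' @exportClass SegmentationMask
setClass("SegmentationMask", contains = "DensityVolume")

setValidity("SegmentationMask", function(object) {
    rng <- range(object@data)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
        "mask values must lie in [0, 1]" else TRUE
})

#' Construct a SegmentationMask
#'
#' @inheritParams DensityVolume
#' @return A [SegmentationMask-class] object.
#' @export
SegmentationMask <- function(data, voxelSize = 1, origin = c(0, 0, 0),
                             label = "") {
    new("SegmentationMask", data = data, voxelSize = as.numeric(voxelSize),
        origin = as.numeric(origin), label = label)
}

#' TriMesh: a triangulated surface in world coordinates
#'
#' @slot vertices numeric n x 3 matrix, vertex positions in nm.
#' @slot faces integer m x 3 matrix of 1-based vertex indices with
#'   consistent winding per connected component.
#' @slot vertexNormals numeric n x 3 matrix of unit normals, or a 0-row
#'   matrix when normals have not been computed.
#' @exportClass TriMesh
setClass("TriMesh",
    representation(vertices = "matrix", faces = "matrix",
                   vertexNormals = "matrix"),
    prototype(vertexNormals = matrix(numeric(0), 0, 3)))

setValidity("TriMesh", function(object) {
    msg <- NULL
    if (ncol(object@vertices) != 3L) msg <- c(msg, "'vertices' must be n x 3")
    if (ncol(object@faces) != 3L) msg <- c(msg, "'faces' must be m x 3")
    if (nrow(object@faces) > 0) {
        f <- object@faces
        if (min(f) < 1L || max(f) > nrow(object@vertices))
            msg <- c(msg, "face indices out of range")
        if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
            msg <- c(msg, "degenerate faces (repeated vertex index)")
    }
    if (nrow(object@vertexNormals) > 0) {
        if (nrow(object@vertexNormals) != nrow(object@vertices))
            msg <- c(msg, "'vertexNormals' must match vertex count")
        else {
            nn <- sqrt(rowSums(object@vertexNormals^2))
            if (any(abs(nn - 1) > 1e-6))
                msg <- c(msg, "vertex normals must be unit length")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a TriMesh
#'
#' @param vertices n x 3 numeric matrix (nm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param vertexNormals optional n x 3 matrix of unit normals.
#' @return A [TriMesh-class] object.
#' @export
TriMesh <- function(vertices, faces,
                    vertexNormals = matrix(numeric(0), 0, 3)) {
    storage.mode(faces) <- "integer"
    new("TriMesh", vertices = as.matrix(vertices), faces = faces,
        vertexNormals = as.matrix(vertexNormals))
}

#' PoseSet: particle positions and orientations
#'
#' Positions are stored in world nanometres; rotations are proper 3x3
#' matrices mapping the particle frame to the world frame.  The on-disk
#' representation (voxel positions, Euler angles) is handled by
#' [readPoseTable()] / [writePoseTable()].
#'
#' @slot positions numeric n x 3 matrix (nm).
#' @slot rotations numeric 3 x 3 x n array of rotation matrices.
#' @slot score numeric(n) per-particle score (NA when absent).
#' @slot classLabel character(n) class labels.
#' @slot tomogramId character(n) tomogram identifiers.
#' @slot voxelSize voxel size (nm) used for voxel/nm conversion at I/O.
#' @exportClass PoseSet
setClass("PoseSet",
    representation(positions = "matrix", rotations = "array",
                   score = "numeric", classLabel = "character",
                   tomogramId = "character", voxelSize = "numeric"),
    prototype(voxelSize = 1))

setValidity("PoseSet", function(object) {
    msg <- NULL
    n <- nrow(object@positions)
    if (ncol(object@positions) != 3L) msg <- c(msg, "'positions' must be n x 3")
    d <- dim(object@rotations)
    if (length(d) != 3L || d[1] != 3L || d[2] != 3L || d[3] != n)
        msg <- c(msg, "'rotations' must be a 3 x 3 x n array")
    else if (n > 0) {
        for (i in seq_len(n)) {
            R <- object@rotations[, , i]
            if (max(abs(crossprod(R) - diag(3))) > 1e-6 ||
                abs(det(R) - 1) > 1e-6) {
                msg <- c(msg, sprintf("rotation %d is not a proper rotation", i))
                break
            }
        }
    }
    if (length(object@score) != n) msg <- c(msg, "'score' length mismatch")
    if (length(object@classLabel) != n) msg <- c(msg, "'classLabel' length mismatch")
    if (length(object@tomogramId) != n) msg <- c(msg, "'tomogramId' length mismatch")
    if (any(!is.finite(object@positions))) msg <- c(msg, "non-finite positions")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PoseSet
#'
#' @param positions n x 3 matrix of world positions (nm).
#' @param rotations 3 x 3 x n array of proper rotation matrices
#'   (particle frame to world frame).
#' @param score optional numeric per-particle score.
#' @param classLabel optional character class labels.
#' @param tomogramId optional tomogram identifiers (single value recycled).
#' @param voxelSize voxel size (nm) for on-disk voxel coordinates.
#' @return A [PoseSet-class] object.
#' @export
PoseSet <- function(positions, rotations, score = NULL, classLabel = NULL,
                    tomogramId = "tomo_1", voxelSize = 1) {
    positions <- as.matrix(positions)
    n <- nrow(positions)
    if (is.null(score)) score <- rep(NA_real_, n)
    if (is.null(classLabel)) classLabel <- rep("", n)
    if (length(tomogramId) == 1L) tomogramId <- rep(tomogramId, n)
    new("PoseSet", positions = positions, rotations = rotations,
        score = as.numeric(score), classLabel = as.character(classLabel),
        tomogramId = as.character(tomogramId),
        voxelSize = as.numeric(voxelSize))
}

#' CurvatureField: per-vertex curvature of a triangular mesh
#'
#' Principal curvatures are ordered `k1 >= k2` (signed).  The sign
#' convention follows the vertex normals: a surface bulging toward its
#' normal has positive mean curvature, an indentation negative.
#'
#' @slot k1,k2 numeric principal curvatures (1/nm).
#' @slot H numeric mean curvature, `0.5 * (k1 + k2)` (1/nm).
#' @slot K numeric Gaussian curvature, `k1 * k2` (1/nm^2).
#' @slot e1,e2 n x 3 matrices of unit principal directions.
#' @slot voronoiArea numeric mixed Voronoi vertex areas (nm^2).
#' @exportClass CurvatureField
setClass("CurvatureField",
    representation(k1 = "numeric", k2 = "numeric", H = "numeric",
                   K = "numeric", e1 = "matrix", e2 = "matrix",
                   voronoiArea = "numeric"))

setValidity("CurvatureField", function(object) {
    msg <- NULL
    n <- length(object@k1)
    ok <- is.finite(object@k1) & is.finite(object@k2)
    if (any(object@k1[ok] < object@k2[ok] - 1e-9))
        msg <- c(msg, "k1 must be >= k2")
    if (max(abs(object@H - 0.5 * (object@k1 + object@k2)), na.rm = TRUE) > 1e-12)
        msg <- c(msg, "H must equal 0.5 * (k1 + k2)")
    if (max(abs(object@K - object@k1 * object@k2), na.rm = TRUE) > 1e-12)
        msg <- c(msg, "K must equal k1 * k2")
    if (any(object@voronoiArea[is.finite(object@voronoiArea)] <= 0))
        msg <- c(msg, "voronoiArea must be positive")
    if (nrow(object@e1) != n || nrow(object@e2) != n)
        msg <- c(msg, "direction matrices must match vertex count")
    if (is.null(msg)) TRUE else msg
})
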