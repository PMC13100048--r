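# Particle pose tables: tab-separated motive-list dialect with header
#   tomogram_id x y z phi theta psi score class
# Positions on disk are in voxels, angles in degrees (intrinsic ZXZ by
# default).  In memory poses are world-nm positions plus rotation matrices.

.poseColumns <- c("tomogram_id", "x", "y", "z", "phi", "theta", "psi",
                  "score", "class")

#' Read a particle pose table
#'
#' Positions are converted from voxel units to world nm using the
#' half-voxel convention (`world = (pos + 0.5) * voxelSize`), and Euler
#' triples to rotation matrices.
#'
#' @param path tab-separated file with columns
#'   `tomogram_id x y z phi theta psi score class`.
#' @param voxelSize voxel size in nm used for the conversion.
#' @param convention on-disk Euler convention; only `"zxz"` (intrinsic,
#'   degrees) is implemented.
#' @return A [PoseSet-class].
#' @export
readPoseTable <- function(path, voxelSize = 1, convention = "zxz") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    missing <- setdiff(.poseColumns, names(tab))
    if (length(missing) > 0)
        stop("pose table '", path, "' is missing columns: ",
             paste(missing, collapse = ", "),
             "; expected header: ", paste(.poseColumns, collapse = " "))
    n <- nrow(tab)
    rot <- array(0, c(3, 3, n))
    for (i in seq_len(n))
        rot[, , i] <- eulerToMatrix(tab$phi[i], tab$theta[i], tab$psi[i],
                                    convention = convention)
    pos <- (as.matrix(tab[, c("x", "y", "z")]) + 0.5) * voxelSize
    dimnames(pos) <- NULL
    PoseSet(pos, rot, score = tab$score, classLabel = tab$class,
            tomogramId = tab$tomogram_id, voxelSize = voxelSize)
}

#' Write a particle pose table
#'
#' Inverse of [readPoseTable()]: world-nm positions back to voxels,
#' rotation matrices back to Euler triples.  A read-write-read cycle
#' preserves rotation matrices to better than 1e-6 degrees.
#'
#' @param poses a [PoseSet-class].
#' @param path output path.
#' @param convention Euler convention tag (see [readPoseTable()]).
#' @return Invisibly, `path`.
#' @export
writePoseTable <- function(poses, path, convention = "zxz") {
    n <- length(poses)
    ang <- matrix(0, n, 3)
    for (i in seq_len(n))
        ang[i, ] <- matrixToEuler(poses@rotations[, , i],
                                  convention = convention)
    pos <- poses@positions / poses@voxelSize - 0.5
    num <- function(x) sprintf("%.17g", x)   # lossless double round-trip
    tab <- data.frame(tomogram_id = poses@tomogramId,
                      x = num(pos[, 1]), y = num(pos[, 2]),
                      z = num(pos[, 3]), phi = num(ang[, 1]),
                      theta = num(ang[, 2]), psi = num(ang[, 3]),
                      score = num(poses@score), class = poses@classLabel)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
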