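#' @include AllClasses.R
NULL

#' Accessors for volumes, meshes and pose sets
#'
#' @param object a tomoscape object.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("vertexNormals", function(object) standardGeneric("vertexNormals"))
#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("rotations", function(object) standardGeneric("rotations"))
#' @rdname accessors
#' @export
setGeneric("tomogramId", function(object) standardGeneric("tomogramId"))
#' @rdname accessors
#' @export
setGeneric("particleClass", function(object) standardGeneric("particleClass"))
#' @rdname accessors
#' @export
setGeneric("principalCurvatures",
           function(object) standardGeneric("principalCurvatures"))
#' @rdname accessors
#' @export
setGeneric("meanCurvature", function(object) standardGeneric("meanCurvature"))
#' @rdname accessors
#' @export
setGeneric("gaussianCurvature",
           function(object) standardGeneric("gaussianCurvature"))
#' @rdname accessors
#' @export
setGeneric("voronoiAreas", function(object) standardGeneric("voronoiAreas"))

#' @rdname accessors
setMethod("voxelData", "DensityVolume", function(object) object@data)
#' @rdname accessors
setMethod("voxelSize", "DensityVolume", function(object) object@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "PoseSet", function(object) object@voxelSize)
#' @rdname accessors
setMethod("origin", "DensityVolume", function(object) object@origin)
#' @rdname accessors
setMethod("vertices", "TriMesh", function(object) object@vertices)
#' @rdname accessors
setMethod("faces", "TriMesh", function(object) object@faces)
#' @rdname accessors
setMethod("vertexNormals", "TriMesh", function(object) object@vertexNormals)
#' @rdname accessors
setMethod("positions", "PoseSet", function(object) object@positions)
#' @rdname accessors
setMethod("rotations", "PoseSet", function(object) object@rotations)
#' @rdname accessors
setMethod("tomogramId", "PoseSet", function(object) object@tomogramId)
#' @rdname accessors
setMethod("particleClass", "PoseSet", function(object) object@classLabel)
#' @rdname accessors
setMethod("principalCurvatures", "CurvatureField",
          function(object) cbind(k1 = object@k1, k2 = object@k2))
#' @rdname accessors
setMethod("meanCurvature", "CurvatureField", function(object) object@H)
#' @rdname accessors
setMethod("gaussianCurvature", "CurvatureField", function(object) object@K)
#' @rdname accessors
setMethod("voronoiAreas", "CurvatureField", function(object) object@voronoiArea)

#' @rdname accessors
#' @export
setMethod("length", "PoseSet", function(x) nrow(x@positions))

#' Subset a PoseSet
#'
#' @param x a [PoseSet-class].
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PoseSet", function(x, i, j, ..., drop = FALSE) {
    PoseSet(x@positions[i, , drop = FALSE],
            x@rotations[, , i, drop = FALSE],
            score = x@score[i], classLabel = x@classLabel[i],
            tomogramId = x@tomogramId[i], voxelSize = x@voxelSize)
})

setMethod("show", "DensityVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("%s of %d x %d x %d voxels, %.4g nm/voxel\n",
                class(object), d[1], d[2], d[3], object@voxelSize))
    cat(sprintf("  intensity range [%.4g, %.4g]", min(object@data),
                max(object@data)))
    if (nzchar(object@label)) cat("  label:", object@label)
    cat("\n")
})

setMethod("show", "TriMesh", function(object) {
    cat(sprintf("TriMesh: %d vertices, %d faces%s\n",
                nrow(object@vertices), nrow(object@faces),
                if (nrow(object@vertexNormals) > 0) ", with normals" else ""))
})

setMethod("show", "PoseSet", function(object) {
    cat(sprintf("PoseSet of %d particles in %d tomogram(s)\n",
                length(object), length(unique(object@tomogramId))))
})

setMethod("show", "CurvatureField", function(object) {
    cat(sprintf("CurvatureField over %d vertices\n", length(object@k1)))
    cat(sprintf("  median H = %.4g 1/nm, median K = %.4g 1/nm^2\n",
                stats::median(object@H, na.rm = TRUE),
                stats::median(object@K, na.rm = TRUE)))
})

#' Convert a CurvatureField to a data.frame
#'
#' @param x a [CurvatureField-class].
#' @param ... ignored.
#' @return data.frame with columns k1, k2, H, K, voronoiArea.
#' @export
as.data.frame.CurvatureField <- function(x, ...) {
    data.frame(k1 = x@k1, k2 = x@k2, H = x@H, K = x@K,
               voronoiArea = x@voronoiArea)
}
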