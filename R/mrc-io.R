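# MRC2014 volume I/O.  Volumes are stored as mode-2 (float32)
# little-endian; the voxel size is carried in the cell dimensions
# (Angstrom on disk, nm in memory).

#' Read a density volume from an MRC file
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16), the
#' common tomography modes.  The voxel size is taken from the cell
#' dimensions divided by the grid sampling; anisotropic voxel sizes are
#' rejected.  Angstrom header units are converted to nm.
#'
#' @param path file path.
#' @param label optional free-text label for the volume.
#' @return A [DensityVolume-class].
#' @seealso [writeMRC()]
#' @export
readMRC <- function(path, label = basename(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
    if (length(hdr) < 10)
        stop("truncated MRC header in '", path, "'")
    nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
    mx <- hdr[8]; my <- hdr[9]; mz <- hdr[10]
    if (nx <= 0 || ny <= 0 || nz <= 0 || any(c(mx, my, mz) <= 0))
        stop("malformed MRC header in '", path, "'")
    cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
    invisible(readBin(con, "raw", n = 4 * (49 - 13)))   # skip words 14-49
    orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
    invisible(readBin(con, "raw", n = 1024 - 4 * 52))
    vs <- cella / c(mx, my, mz) / 10   # Angstrom -> nm
    if (any(!is.finite(vs)) || any(vs <= 0)) vs <- c(1, 1, 1)
    if (max(vs) - min(vs) > 1e-4 * max(vs))
        stop("anisotropic voxel size unsupported: ",
             paste(signif(vs, 6), collapse = " x "), " nm")
    nvox <- as.double(nx) * ny * nz
    data <- switch(as.character(mode),
        "0" = readBin(con, "integer", n = nvox, size = 1, signed = TRUE,
                      endian = "little"),
        "1" = readBin(con, "integer", n = nvox, size = 2, signed = TRUE,
                      endian = "little"),
        "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
        "6" = readBin(con, "integer", n = nvox, size = 2, signed = FALSE,
                      endian = "little"),
        stop("unsupported MRC mode ", mode, " in '", path, "'"))
    if (length(data) < nvox)
        stop("truncated MRC data in '", path, "': expected ", nvox,
             " voxels, got ", length(data))
    DensityVolume(array(as.numeric(data), dim = c(nx, ny, nz)),
                  voxelSize = vs[1], origin = orig / 10, label = label)
}

#' Write a density volume to an MRC file
#'
#' Writes MRC2014 mode 2 (float32, little-endian) with the voxel size in
#' the cell-dimension fields and the world origin in the origin fields
#' (both in Angstrom on disk).
#'
#' @param volume a [DensityVolume-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMRC <- function(volume, path) {
    stopifnot(is(volume, "DensityVolume"))
    d <- dim(volume@data)
    con <- file(path, "wb")
    on.exit(close(con))
    wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                                 endian = "little")
    wFlt <- function(x) writeBin(as.numeric(x), con, size = 4,
                                 endian = "little")
    wInt(d)                              # NX NY NZ
    wInt(2)                              # MODE
    wInt(c(0, 0, 0))                     # NxSTART
    wInt(d)                              # MX MY MZ
    wFlt(d * volume@voxelSize * 10)      # CELLA (Angstrom)
    wFlt(c(90, 90, 90))                  # CELLB
    wInt(c(1, 2, 3))                     # MAPC MAPR MAPS
    wFlt(c(min(volume@data), max(volume@data), mean(volume@data)))
    wInt(c(1, 0))                        # ISPG, NSYMBT
    wInt(c(0, 0, 0))                     # EXTRA words 25-26, EXTTYP
    wInt(20140)                          # NVERSION (word 28)
    wInt(rep(0, 49 - 28))                # EXTRA words 29-49
    wFlt(volume@origin * 10)             # ORIGIN (Angstrom)
    writeBin(charToRaw("MAP "), con)
    writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
    wFlt(stats::sd(volume@data))
    wInt(0)                              # NLABL
    writeBin(raw(1024 - 4 * 56), con)
    writeBin(as.numeric(volume@data), con, size = 4, endian = "little")
    invisible(path)
}
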