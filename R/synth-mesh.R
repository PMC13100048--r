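# Parametric oracle meshes (plane, sphere, cylinder, saddle) with
# analytic per-vertex curvature.  Sign convention matches the curvature
# estimator: with the supplied normals, a surface bulging toward its
# normal has positive curvature (outward-normaled sphere: k1 = k2 = 1/R).

#' Specification of a parametric oracle mesh
#'
#' @param kind one of `"plane"`, `"sphere"`, `"cylinder"`, `"saddle"`.
#' @param radius radius R in nm (sphere/cylinder) or the saddle scale c
#'   in `z = (x^2 - y^2) / (2c)`.
#' @param extent lateral extent in nm (plane/saddle edge length,
#'   cylinder height).
#' @param targetVertexCount approximate number of vertices.
#' @param jitterSd Gaussian vertex jitter (nm); jittered vertices are
#'   re-projected onto the analytic surface so the analytic curvature
#'   remains exact at the final positions.
#' @param seed integer seed.
#' @return A validated `MeshSpec` list.
#' @export
meshSpec <- function(kind = c("plane", "sphere", "cylinder", "saddle"),
                     radius = 10, extent = 20, targetVertexCount = 1000,
                     jitterSd = 0, seed = 1) {
    kind <- match.arg(kind)
    if (radius <= 0) stop("'radius' must be > 0")
    if (jitterSd < 0) stop("'jitterSd' must be >= 0")
    structure(list(kind = kind, radius = radius, extent = extent,
                   targetVertexCount = as.integer(targetVertexCount),
                   jitterSd = jitterSd, seed = as.integer(seed)),
              class = "MeshSpec")
}

# icosahedron with outward-wound faces, unit radius
.icosahedron <- function() {
    t <- (1 + sqrt(5)) / 2
    v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
               c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
               c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
    v <- v / sqrt(1 + t^2)
    f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11),
               c(1, 11, 12), c(2, 6, 10), c(6, 12, 5), c(12, 11, 3),
               c(11, 8, 7), c(8, 2, 9), c(4, 10, 5), c(4, 5, 3),
               c(4, 3, 7), c(4, 7, 9), c(4, 9, 10), c(5, 10, 6),
               c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
    list(v = v, f = f)
}

# one 4-to-1 subdivision round on the unit sphere
.subdivideSphere <- function(v, f) {
    edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    keys <- c(edgeKey(f[, 1], f[, 2]), edgeKey(f[, 2], f[, 3]),
              edgeKey(f[, 3], f[, 1]))
    uk <- unique(keys)
    mid <- match(keys, uk) + nrow(v)
    pairs <- do.call(rbind, strsplit(uk, " "))
    a <- as.integer(pairs[, 1]); b <- as.integer(pairs[, 2])
    mv <- .rowUnit((v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2)
    nf <- nrow(f)
    m12 <- mid[seq_len(nf)]
    m23 <- mid[nf + seq_len(nf)]
    m31 <- mid[2 * nf + seq_len(nf)]
    f2 <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
                cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
    list(v = rbind(v, mv), f = f2)
}

.icosphere <- function(targetVertexCount) {
    ico <- .icosahedron()
    while (nrow(ico$v) < targetVertexCount)
        ico <- .subdivideSphere(ico$v, ico$f)
    ico
}

# regular grid triangulation of an nu x nv parameter grid; wrap closes u
.gridFaces <- function(nu, nv, wrapU = FALSE) {
    id <- function(i, j) (j - 1) * nu + i
    iu <- if (wrapU) nu else nu - 1
    f <- matrix(0L, 0, 3)
    i <- rep(seq_len(iu), nv - 1)
    j <- rep(seq_len(nv - 1), each = iu)
    i2 <- if (wrapU) ifelse(i == nu, 1L, i + 1L) else i + 1L
    rbind(cbind(id(i, j), id(i2, j), id(i2, j + 1)),
          cbind(id(i, j), id(i2, j + 1), id(i, j + 1)))
}

#' Generate a parametric mesh with analytic curvature
#'
#' Builds a triangulated plane, sphere (subdivided icosahedron), cylinder
#' or saddle with consistent outward/upward orientation, optional vertex
#' jitter (re-projected onto the surface), analytic vertex normals and
#' analytic principal/mean/Gaussian curvature at the final vertex
#' positions.
#'
#' @param spec a [meshSpec()].
#' @return list with `mesh` ([TriMesh-class], normals set to the analytic
#'   normals), `k1`, `k2`, `H`, `K` (numeric per vertex), and `spec`.
#' @export
makeParametricMesh <- function(spec) {
    stopifnot(inherits(spec, "MeshSpec"))
    set.seed(deriveSeed(spec$seed, paste0("mesh-", spec$kind)))
    n <- spec$targetVertexCount
    R <- spec$radius; L <- spec$extent
    jit <- function(m, sd) if (sd > 0)
        m + matrix(stats::rnorm(length(m), sd = sd), nrow(m), 3) else m

    if (spec$kind == "sphere") {
        ico <- .icosphere(n)
        v <- .rowUnit(jit(ico$v * R, spec$jitterSd)) * R
        nv <- nrow(v)
        normals <- v / R
        k1 <- k2 <- rep(1 / R, nv)
        faces <- ico$f
    } else if (spec$kind == "plane") {
        ns <- max(2L, ceiling(sqrt(n)))
        g <- seq(0, L, length.out = ns)
        vv <- as.matrix(expand.grid(x = g, y = g))
        v <- cbind(vv, 0)
        if (spec$jitterSd > 0)
            v[, 1:2] <- v[, 1:2] +
                matrix(stats::rnorm(2 * nrow(v), sd = spec$jitterSd),
                       ncol = 2)
        faces <- .gridFaces(ns, ns)
        normals <- matrix(rep(c(0, 0, 1), each = nrow(v)), ncol = 3)
        k1 <- k2 <- rep(0, nrow(v))
    } else if (spec$kind == "cylinder") {
        ntheta <- max(8L, round(sqrt(n * 2 * pi * R / L)))
        nz <- max(2L, round(n / ntheta))
        th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
        zz <- seq(0, L, length.out = nz)
        grid <- expand.grid(th = th, z = zz)
        v <- cbind(R * cos(grid$th), R * sin(grid$th), grid$z)
        v <- jit(v, spec$jitterSd)
        rad <- sqrt(v[, 1]^2 + v[, 2]^2)
        v[, 1] <- v[, 1] / rad * R
        v[, 2] <- v[, 2] / rad * R
        faces <- .gridFaces(ntheta, nz, wrapU = TRUE)
        normals <- cbind(v[, 1] / R, v[, 2] / R, 0)
        k1 <- rep(1 / R, nrow(v))
        k2 <- rep(0, nrow(v))
    } else {   # saddle: z = (x^2 - y^2) / (2c), c = radius
        ns <- max(2L, ceiling(sqrt(n)))
        g <- seq(-L / 2, L / 2, length.out = ns)
        vv <- as.matrix(expand.grid(x = g, y = g))
        if (spec$jitterSd > 0)
            vv <- vv + matrix(stats::rnorm(length(vv), sd = spec$jitterSd),
                              ncol = 2)
        cc <- R
        z <- (vv[, 1]^2 - vv[, 2]^2) / (2 * cc)
        v <- cbind(vv, z)
        faces <- .gridFaces(ns, ns)
        fx <- vv[, 1] / cc; fy <- -vv[, 2] / cc
        w2 <- 1 + fx^2 + fy^2
        normals <- cbind(-fx, -fy, 1) / sqrt(w2)
        # graph curvature with upward normal, estimator sign convention
        K <- (-1 / cc^2) / w2^2
        Hg <- ((1 + fy^2) / cc - (1 + fx^2) / cc) / (2 * w2^1.5)
        H <- -Hg
        disc <- sqrt(pmax(0, H^2 - K))
        k1 <- H + disc; k2 <- H - disc
    }

    mesh <- TriMesh(v, faces, vertexNormals = .rowUnit(normals))
    mesh <- .orientFaces(mesh)
    H <- 0.5 * (k1 + k2)
    K <- k1 * k2
    list(mesh = mesh, k1 = k1, k2 = k2, H = H, K = K, spec = spec)
}

# make face winding agree with the vertex normals
.orientFaces <- function(mesh) {
    v <- mesh@vertices; f <- mesh@faces
    e1 <- v[f[, 2], ] - v[f[, 1], ]
    e2 <- v[f[, 3], ] - v[f[, 1], ]
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    vn <- mesh@vertexNormals
    ref <- (vn[f[, 1], ] + vn[f[, 2], ] + vn[f[, 3], ]) / 3
    flip <- rowSums(fn * ref) < 0
    f[flip, ] <- f[flip, c(1, 3, 2)]
    TriMesh(v, f, vertexNormals = vn)
}
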