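# Per-vertex curvature on irregular triangular meshes: per-face second
# fundamental form by least-squares fitting of vertex-normal differences
# across the triangle edges, accumulated at vertices with mixed-Voronoi
# area weights, then eigen-decomposed into principal curvatures.
#
# Sign convention: with the supplied vertex normals, normals spreading
# apart along an edge (convex, bulging toward the normal) give positive
# curvature; an indented surface gives negative mean curvature.

.crossRows <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-face curvature tensors
#'
#' For each face, solves in least squares over the three edges
#' `II %*% e = dn` (edge vectors and vertex-normal differences projected
#' into the face tangent frame) for the symmetric 2x2 second fundamental
#' form (3 unknowns, 6 equations).
#'
#' @param mesh a [TriMesh-class] with vertex normals.
#' @return list with `tensors` (m x 3 matrix of components a, b, c of
#'   `[[a, b], [b, c]]`), `frameU`, `frameV`, `normal` (m x 3 face tangent
#'   frames), `area` (face areas).
#' @export
faceCurvatureTensors <- function(mesh) {
    v <- mesh@vertices; f <- mesh@faces
    if (nrow(mesh@vertexNormals) == 0)
        stop("mesh has no vertex normals; run refineNormals() first")
    vn <- mesh@vertexNormals
    p0 <- v[f[, 1], , drop = FALSE]
    p1 <- v[f[, 2], , drop = FALSE]
    p2 <- v[f[, 3], , drop = FALSE]
    n0 <- vn[f[, 1], , drop = FALSE]
    n1 <- vn[f[, 2], , drop = FALSE]
    n2 <- vn[f[, 3], , drop = FALSE]
    fn <- .crossRows(p1 - p0, p2 - p0)
    a2 <- sqrt(rowSums(fn^2))
    if (any(a2 < 1e-18)) stop("near-zero-area face encountered")
    nf <- fn / a2
    u <- p1 - p0
    u <- u - nf * rowSums(u * nf)
    u <- u / sqrt(rowSums(u^2))
    w <- .crossRows(nf, u)
    # the three directed edges and their normal differences
    E <- list(p1 - p0, p2 - p1, p0 - p2)
    D <- list(n1 - n0, n2 - n1, n0 - n2)
    A11 <- A12 <- A22b <- A23 <- A33 <- 0
    b1 <- b2 <- b3 <- 0
    for (k in 1:3) {
        eu <- rowSums(E[[k]] * u); ev <- rowSums(E[[k]] * w)
        du <- rowSums(D[[k]] * u); dv <- rowSums(D[[k]] * w)
        A11 <- A11 + eu^2
        A12 <- A12 + eu * ev
        A22b <- A22b + ev^2
        b1 <- b1 + eu * du
        b2 <- b2 + ev * du + eu * dv
        b3 <- b3 + ev * dv
    }
    # normal equations of the 6x3 system
    # rows: (eu, ev, 0) -> du ; (0, eu, ev) -> dv
    M11 <- A11; M12 <- A12; M13 <- 0 * A11
    M22 <- A22b + A11; M23 <- A12; M33 <- A22b
    det3 <- M11 * (M22 * M33 - M23 * M23) -
            M12 * (M12 * M33 - M23 * M13) +
            M13 * (M12 * M23 - M22 * M13)
    i11 <- (M22 * M33 - M23^2) / det3
    i12 <- -(M12 * M33 - M13 * M23) / det3
    i13 <- (M12 * M23 - M13 * M22) / det3
    i22 <- (M11 * M33 - M13^2) / det3
    i23 <- -(M11 * M23 - M12 * M13) / det3
    i33 <- (M11 * M22 - M12^2) / det3
    ta <- i11 * b1 + i12 * b2 + i13 * b3
    tb <- i12 * b1 + i22 * b2 + i23 * b3
    tc <- i13 * b1 + i23 * b2 + i33 * b3
    list(tensors = cbind(a = ta, b = tb, c = tc),
         frameU = u, frameV = w, normal = nf, area = a2 / 2)
}

# mixed-Voronoi corner areas per face (Meyer et al. rule: plain Voronoi
# for non-obtuse triangles, area/2 at the obtuse corner and area/4
# elsewhere for obtuse ones) -- keeps all weights positive
.mixedVoronoiCornerAreas <- function(mesh) {
    v <- mesh@vertices; f <- mesh@faces
    P <- list(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
              v[f[, 3], , drop = FALSE])
    cot <- matrix(0, nrow(f), 3)
    len2 <- matrix(0, nrow(f), 3)   # squared edge length opposite corner k
    for (k in 1:3) {
        a <- P[[k]]; b <- P[[k %% 3 + 1]]; cc <- P[[(k + 1) %% 3 + 1]]
        u <- b - a; w <- cc - a
        cr <- sqrt(rowSums(.crossRows(u, w)^2))
        cot[, k] <- rowSums(u * w) / cr
        len2[, k] <- rowSums((b - cc)^2)
    }
    area <- 0.5 * sqrt(rowSums(.crossRows(P[[2]] - P[[1]],
                                          P[[3]] - P[[1]])^2))
    corner <- matrix(0, nrow(f), 3)
    for (k in 1:3) {
        kn <- k %% 3 + 1; kp <- (k + 1) %% 3 + 1
        # Voronoi area at corner k uses cotangents at the two other corners
        corner[, k] <- (len2[, kp] * cot[, kp] + len2[, kn] * cot[, kn]) / 8
    }
    obtuse <- cot < 0   # cot of an angle > 90 degrees is negative
    anyObt <- rowSums(obtuse) > 0
    for (k in 1:3) {
        corner[anyObt, k] <- ifelse(obtuse[anyObt, k],
                                    area[anyObt] / 2, area[anyObt] / 4)
    }
    corner
}

# Rodrigues rotation of row vectors w about the rotation taking a -> b
.rotateRowsFromTo <- function(w, a, b) {
    axis <- .crossRows(a, b)
    s <- sqrt(rowSums(axis^2))
    c0 <- rowSums(a * b)
    out <- w
    ok <- s > 1e-12
    if (any(ok)) {
        u <- axis[ok, , drop = FALSE] / s[ok]
        wk <- w[ok, , drop = FALSE]
        ck <- c0[ok]; sk <- s[ok]
        uxw <- .crossRows(u, wk)
        udw <- rowSums(u * wk)
        out[ok, ] <- wk * ck + uxw * sk + u * (udw * (1 - ck))
    }
    flipped <- !ok & c0 < 0
    if (any(flipped)) {
        # antiparallel normals: reflect through the target plane
        bb <- b[flipped, , drop = FALSE]
        wk <- w[flipped, , drop = FALSE]
        out[flipped, ] <- wk - 2 * bb * rowSums(bb * wk)
    }
    out
}

#' Accumulate face curvature tensors at vertices
#'
#' Each face tensor is re-expressed in the tangent frame of each incident
#' vertex (frame transport by the minimal rotation between the face and
#' vertex normals) and averaged with the vertex's mixed-Voronoi corner
#' area inside that face.
#'
#' @param mesh a [TriMesh-class] with vertex normals.
#' @param faceTensors result of [faceCurvatureTensors()] (computed when
#'   NULL).
#' @return list with `tensors` (n x 3 vertex tensor components in the
#'   vertex frames), `frameU`, `frameV` (n x 3 vertex tangent frames),
#'   `voronoiArea` (numeric n).
#' @export
accumulateVertexTensors <- function(mesh, faceTensors = NULL) {
    if (is.null(faceTensors)) faceTensors <- faceCurvatureTensors(mesh)
    v <- mesh@vertices; f <- mesh@faces
    vn <- mesh@vertexNormals
    n <- nrow(v)
    # vertex tangent frames
    ref <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
    swap <- abs(vn[, 1]) > 0.9
    ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
    uV <- ref - vn * rowSums(ref * vn)
    uV <- uV / sqrt(rowSums(uV^2))
    wV <- .crossRows(vn, uV)
    cornerA <- .mixedVoronoiCornerAreas(mesh)
    accA <- accB <- accC <- accW <- rep(0, n)
    for (k in 1:3) {
        vi <- f[, k]
        nf <- faceTensors$normal
        # transport vertex frame into the face tangent plane
        u1 <- .rotateRowsFromTo(uV[vi, , drop = FALSE],
                                vn[vi, , drop = FALSE], nf)
        w1 <- .rotateRowsFromTo(wV[vi, , drop = FALSE],
                                vn[vi, , drop = FALSE], nf)
        x1u <- rowSums(u1 * faceTensors$frameU)
        x1v <- rowSums(u1 * faceTensors$frameV)
        x2u <- rowSums(w1 * faceTensors$frameU)
        x2v <- rowSums(w1 * faceTensors$frameV)
        ta <- faceTensors$tensors[, "a"]
        tb <- faceTensors$tensors[, "b"]
        tc <- faceTensors$tensors[, "c"]
        q11 <- ta * x1u^2 + 2 * tb * x1u * x1v + tc * x1v^2
        q12 <- ta * x1u * x2u + tb * (x1u * x2v + x1v * x2u) +
               tc * x1v * x2v
        q22 <- ta * x2u^2 + 2 * tb * x2u * x2v + tc * x2v^2
        wgt <- cornerA[, k]
        tmp <- rowsum(cbind(q11, q12, q22, 1) * wgt, vi, reorder = FALSE)
        tgt <- as.integer(rownames(tmp))
        accA[tgt] <- accA[tgt] + tmp[, 1]
        accB[tgt] <- accB[tgt] + tmp[, 2]
        accC[tgt] <- accC[tgt] + tmp[, 3]
        accW[tgt] <- accW[tgt] + tmp[, 4]
    }
    bad <- accW <= 0
    accW[bad] <- NA
    list(tensors = cbind(a = accA / accW, b = accB / accW,
                         c = accC / accW),
         frameU = uV, frameV = wV, voronoiArea = accW)
}

#' Per-vertex principal, mean and Gaussian curvature
#'
#' Eigen-decomposes the accumulated vertex curvature tensors.  Principal
#' curvatures are ordered `k1 >= k2`; `H = 0.5 * (k1 + k2)` and
#' `K = k1 * k2` by definition.  With normals oriented toward the
#' reference (e.g. cytosol-facing) side, bulges toward the normal have
#' positive H and indentations negative H.
#'
#' @param mesh a [TriMesh-class]; vertex normals are computed with
#'   [refineNormals()] when absent.
#' @param refineIterations normal-refinement rounds when normals must be
#'   computed.
#' @return A [CurvatureField-class].
#' @examples
#' sph <- makeParametricMesh(meshSpec("sphere", radius = 10,
#'                                    targetVertexCount = 642))
#' cf <- curvatureField(sph$mesh)
#' median(meanCurvature(cf))   # close to 1/10
#' @export
curvatureField <- function(mesh, refineIterations = 0) {
    if (nrow(mesh@vertexNormals) == 0)
        mesh <- refineNormals(mesh, iterations = refineIterations)
    if (any(!is.finite(mesh@vertexNormals)))
        stop("non-finite vertex normals")
    acc <- accumulateVertexTensors(mesh)
    a <- acc$tensors[, "a"]; b <- acc$tensors[, "b"]; cc <- acc$tensors[, "c"]
    mid <- (a + cc) / 2
    disc <- sqrt(((a - cc) / 2)^2 + b^2)
    k1 <- mid + disc
    k2 <- mid - disc
    theta <- 0.5 * atan2(2 * b, a - cc)
    e1 <- acc$frameU * cos(theta) + acc$frameV * sin(theta)
    e2 <- -acc$frameU * sin(theta) + acc$frameV * cos(theta)
    # deterministic direction signs: first nonzero component positive
    fix <- function(m) {
        sgn <- sign(m[, 1])
        z1 <- sgn == 0
        sgn[z1] <- sign(m[z1, 2])
        z2 <- sgn == 0
        sgn[z2] <- sign(m[z2, 3])
        sgn[sgn == 0] <- 1
        m * sgn
    }
    new("CurvatureField", k1 = k1, k2 = k2, H = 0.5 * (k1 + k2),
        K = k1 * k2, e1 = fix(e1), e2 = fix(e2),
        voronoiArea = acc$voronoiArea)
}
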