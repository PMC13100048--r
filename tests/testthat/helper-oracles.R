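# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# exact two-sided Fisher p by full hypergeometric enumeration
fisherEnumOracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
    xs <- max(0, c1 - r2):min(r1, c1)
    pr <- vapply(xs, function(x)
        exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)),
        numeric(1))
    pObs <- pr[match(a, xs)]
    sum(pr[pr <= pObs * (1 + 1e-7)])
}

# exact two-tailed Mann-Whitney p by brute force over all label
# assignments (small n only)
mwBruteForceOracle <- function(x, y) {
    nx <- length(x); ny <- length(y)
    pool <- c(x, y)
    uOf <- function(idx) {
        r <- rank(pool)
        ux <- sum(r[idx]) - nx * (nx + 1) / 2
        min(ux, nx * ny - ux)
    }
    uObs <- uOf(seq_len(nx))
    combs <- utils::combn(nx + ny, nx)
    us <- apply(combs, 2, uOf)
    # two-tailed: min-U folds both tails, so count once
    min(1, mean(us <= uObs + 1e-9))
}

# closed-form noiseless two-Gaussian bilayer profile (leaflets at
# +-t/2, trough width sigma, depth A); x in nm from the mid-plane
bilayerProfileFun <- function(t, sigma, A = 1) {
    function(x) -A * (exp(-(x - t / 2)^2 / (2 * sigma^2)) +
                      exp(-(x + t / 2)^2 / (2 * sigma^2)))
}

# numerically minimized trough positions of the closed-form profile
bilayerMinimaOracle <- function(t, sigma, A = 1) {
    f <- bilayerProfileFun(t, sigma, A)
    m1 <- stats::optimize(f, c(-t, 0))$minimum
    m2 <- stats::optimize(f, c(0, t))$minimum
    c(m1, m2)
}

# an IntensityProfile built directly from the closed form (no volume)
analyticBilayerProfile <- function(t, sigma, spacing, halfLength,
                                   A = 1) {
    m <- floor(halfLength / spacing)
    pos <- (-m:m) * spacing
    f <- bilayerProfileFun(t, sigma, A)
    structure(list(samples = f(pos), positions = pos, spacing = spacing,
                   axisOrigin = c(0, 0, 0), axisDirection = c(0, 0, 1)),
              class = "IntensityProfile")
}

# total surface area of a mesh
meshArea <- function(mesh) {
    v <- vertices(mesh); f <- faces(mesh)
    e1 <- v[f[, 2], ] - v[f[, 1], ]
    e2 <- v[f[, 3], ] - v[f[, 1], ]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    sum(sqrt(rowSums(cr^2))) / 2
}

# small helper: angular distance between two rotations in degrees
rotDist <- function(R1, R2) rotationAngle(R1 %*% t(R2))
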