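# Independent oracles used to cross-check the package's geometry and
# statistics. Deliberately brute-force / enumeration based so they share no
# code path with the implementations they check.

# Rodrigues rotation of point p about the axis through `origin` with unit
# direction u, by `theta` degrees (right-hand rule)
rotate_about_axis <- function(p, origin, u, theta) {
  th <- theta * pi / 180
  v <- p - origin
  vrot <- v * cos(th) + cross_prod(u, v) * sin(th) + u * sum(u * v) * (1 - cos(th))
  vrot + origin
}

cross_prod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Brute-force dihedral: rotate p4 about the p2->p3 axis until the four
# points become cis-planar (p4's perpendicular component aligned with
# p1's); the rotation angle that achieves it is the dihedral. Coarse grid
# then golden-section refinement.
oracle_dihedral <- function(p1, p2, p3, p4) {
  u <- p3 - p2; u <- u / sqrt(sum(u^2))
  perp_unit <- function(p, origin) {
    v <- p - origin
    w <- v - u * sum(u * v)
    w / sqrt(sum(w^2))
  }
  v1 <- perp_unit(p1, p2)
  misalign <- function(theta) {
    p4r <- rotate_about_axis(p4, p3, u, theta)
    sum((perp_unit(p4r, p3) - v1)^2)
  }
  grid <- seq(-180, 180, by = 0.1)
  vals <- vapply(grid, misalign, numeric(1))
  best <- grid[which.min(vals)]
  opt <- stats::optimize(misalign, c(best - 0.2, best + 0.2), tol = 1e-10)
  # a right-hand rotation of p4 by theta about p2->p3 SUBTRACTS theta from
  # the IUPAC dihedral (positive = clockwise viewed from p2 toward p3), so
  # planar-cis is reached at theta = +dihedral
  ang <- opt$minimum
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

euler_rot <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3)
  Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3)
  Rz1 %*% Ry %*% Rz2
}

# Grid-search superposition oracle: best rmsd over rotations parameterised
# by z-y-z Euler angles (coarse grid, Nelder-Mead refinement); translation
# handled by centering.
oracle_min_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  f <- function(par) {
    R <- euler_rot(par[1], par[2], par[3])
    sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
  }
  step <- 15 * pi / 180
  best <- NULL; bestv <- Inf
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (g in seq(0, 2 * pi - step, by = step)) {
        v <- f(c(a, b, g))
        if (v < bestv) { bestv <- v; best <- c(a, b, g) }
      }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k)
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)),
    numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive exact substring scan (0-based offsets), oracle for the motif search
oracle_exact_scan <- function(seq, pattern) {
  L <- nchar(pattern); n <- nchar(seq)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - L + 1))
    if (substr(seq, i, i + L - 1) == pattern) hits <- c(hits, i - 1L)
  hits
}

random_rigid_motion <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]), 2 * (q[2] * q[4] + q[3] * q[1]),
    2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[2] * q[1]),
    2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, sd = 5))
}
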