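# fixture builders and independent oracles shared across the suite

KE <- 332.0637

make_atoms <- function(n, charge = 0, rmin_half = 1.9, epsilon = 0.1,
                       born_radius = 1.7, partition = "receptor",
                       element = "C", resnum = 1L, name = NULL) {
  data.frame(
    serial = seq_len(n),
    name = if (is.null(name)) paste0("X", seq_len(n)) else name,
    element = rep_len(element, n),
    resnum = rep_len(resnum, n),
    resname = "RES", chain = "A",
    charge = rep_len(charge, n),
    rmin_half = rep_len(rmin_half, n),
    epsilon = rep_len(epsilon, n),
    born_radius = rep_len(born_radius, n),
    partition = rep_len(partition, n),
    stringsAsFactors = FALSE)
}

# single ion fixture
ion_topology <- function(q = 1, radius = 2.0) {
  topology(make_atoms(1L, charge = q, born_radius = radius,
                      partition = "ligand1"))
}

# 5-atom linear chain A-B-C-D-E
chain5_topology <- function(charge = 0) {
  topology(make_atoms(5L, charge = charge),
           bonds = cbind(1:4, 2:5))
}

# benzene-like 6-cycle with given circumradius, centred at `centre`,
# rotated by matrix R
hexagon_coords <- function(centre = c(0, 0, 0), R = diag(3),
                           radius = 1.4) {
  ang <- (0:5) * pi / 3
  pts <- cbind(radius * cos(ang), radius * sin(ang), 0) %*% t(R)
  sweep(pts, 2L, centre, "+")
}

rotation_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rigid <- function() {
  ax <- stats::rnorm(3)
  list(R = rotation_about(ax, stats::runif(1, 0, 360)),
       t = stats::rnorm(3, sd = 5))
}

# two-ring (hexagon + hexagon) topology spanning two partitions
two_ring_topology <- function() {
  at <- rbind(make_atoms(6L, partition = "receptor", resnum = 1L),
              make_atoms(6L, partition = "ligand1", resnum = 101L))
  at$serial <- 1:12
  topology(at, bonds = rbind(cbind(1:6, c(2:6, 1L)),
                             cbind(7:12, c(8:12, 7L))))
}

# ---- independent oracles ------------------------------------------------

# naive triple-nested-loop Coulomb sum (independent of the vectorized path)
naive_coulomb <- function(frame, top, subset = seq_len(nrow(top$atoms))) {
  q <- top$atoms$charge
  excl <- apply(top$exclusions, 1L, paste, collapse = "-")
  s14 <- apply(top$scaled14, 1L, paste, collapse = "-")
  e <- 0
  for (i in subset) for (j in subset) {
    if (j <= i) next
    key <- paste(min(i, j), max(i, j), sep = "-")
    if (key %in% excl) next
    sc <- if (key %in% s14) top$ee_scale else 1
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    e <- e + KE * q[i] * q[j] * sc / r
  }
  e
}

naive_lj <- function(frame, top, subset = seq_len(nrow(top$atoms))) {
  at <- top$atoms
  excl <- apply(top$exclusions, 1L, paste, collapse = "-")
  s14 <- apply(top$scaled14, 1L, paste, collapse = "-")
  e <- 0
  for (i in subset) for (j in subset) {
    if (j <= i) next
    key <- paste(min(i, j), max(i, j), sep = "-")
    if (key %in% excl) next
    sc <- if (key %in% s14) top$vdw_scale else 1
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    rmin <- at$rmin_half[i] + at$rmin_half[j]
    eps <- sqrt(at$epsilon[i] * at$epsilon[j])
    e <- e + sc * eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  e
}

# naive GB double sum from given effective radii
naive_gb <- function(frame, top, subset, radii, eps_in = 1, eps_out = 80) {
  q <- top$atoms$charge[subset]
  m <- length(subset)
  tau <- 1 / eps_in - 1 / eps_out
  e <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    r2 <- sum((frame[subset[i], ] - frame[subset[j], ])^2)
    f <- sqrt(r2 + radii[i] * radii[j] *
                exp(-r2 / (4 * radii[i] * radii[j])))
    e <- e - 0.5 * KE * tau * q[i] * q[j] / f
  }
  e
}

# quadrature oracle for the pairwise descreening integral:
# (1/4pi) * int over sphere (radius sj at distance d) of dV/r^4,
# excluding the region within ri of the origin
descreen_quadrature <- function(ri, d, sj) {
  f <- function(t) {
    cosal <- (d^2 + t^2 - sj^2) / (2 * d * t)
    hfrac <- pmin(pmax((1 - cosal) / 2, 0), 1)
    hfrac * 4 * pi / t^2
  }
  lo <- max(ri, d - sj); hi <- d + sj
  if (hi <= lo) return(0)
  stats::integrate(f, lo, hi, rel.tol = 1e-10)$value / (4 * pi)
}

# brute-force simple-cycle census: every vertex subset of the given size
# that induces a connected 2-regular subgraph is one cycle
brute_force_cycles <- function(bonds, n, sizes = 5:6) {
  adj <- matrix(FALSE, n, n)
  adj[bonds] <- TRUE
  adj[bonds[, c(2, 1), drop = FALSE]] <- TRUE
  out <- list()
  for (sz in sizes) {
    for (combo in utils::combn(n, sz, simplify = FALSE)) {
      sub <- adj[combo, combo, drop = FALSE]
      if (!all(rowSums(sub) == 2)) next
      # connectivity of the 2-regular subgraph
      seen <- 1L
      repeat {
        nxt <- unique(c(seen, which(apply(
          sub[seen, , drop = FALSE], 2L, any))))
        if (length(nxt) == length(seen)) break
        seen <- nxt
      }
      if (length(seen) == sz) out[[length(out) + 1L]] <- combo
    }
  }
  out
}

# brute-force RMSD minimization over rotations (Euler angles, many starts)
brute_force_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2L, colMeans(mobile))
  B <- sweep(reference, 2L, colMeans(reference))
  obj <- function(p) {
    R <- rotation_about(c(1, 0, 0), p[1L]) %*%
      rotation_about(c(0, 1, 0), p[2L]) %*%
      rotation_about(c(0, 0, 1), p[3L])
    sqrt(mean(rowSums((A %*% R - B)^2)))
  }
  best <- Inf
  for (s in seq_len(40)) {
    p0 <- stats::runif(3, 0, 360)
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# small host-guest system: 3-atom charged host triangle + 1-atom guest
host_guest_topology <- function() {
  at <- rbind(
    make_atoms(3L, charge = c(0.3, -0.2, 0.1), rmin_half = 1.9,
               epsilon = 0.12, born_radius = 1.7,
               partition = "receptor", resnum = 1L),
    make_atoms(1L, charge = -0.4, rmin_half = 1.8, epsilon = 0.2,
               born_radius = 1.6, partition = "ligand1", resnum = 101L))
  at$serial <- 1:4
  topology(at, bonds = cbind(c(1L, 2L), c(2L, 3L)))
}

host_guest_frame <- function() {
  rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0), c(0.9, 0.5, 3.4))
}
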