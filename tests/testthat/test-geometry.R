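# geometry_analysis: superposition, rings, stacking, contacts, H-bonds

test_that("kabsch_superpose recovers rigid motions exactly", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0)
  R <- rotation_about(c(0, 0, 1), 90)
  y <- sweep(x %*% t(R), 2L, c(5, 0, 0), "+")
  fit <- kabsch_superpose(y, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("kabsch rmsd equals brute-force minimization on 4-point sets", {
  a <- rbind(c(0, 0, 0), c(1.2, 0.3, -0.5), c(-0.7, 1.9, 0.4),
             c(0.5, -1.1, 1.3))
  b <- rbind(c(0.2, 0.1, 0.0), c(1.0, 0.8, -0.2), c(-1.1, 1.5, 0.9),
             c(0.9, -1.4, 0.8))
  set.seed(7)
  oracle <- brute_force_rmsd(a, b)
  expect_equal(kabsch_superpose(a, b)$rmsd, oracle, tolerance = 1e-6)
})

test_that("kabsch rmsd is invariant under proper rigid transforms", {
  set.seed(2)
  x <- matrix(rnorm(24), 8, 3)
  y <- x + matrix(rnorm(24, sd = 0.3), 8, 3)
  base <- kabsch_superpose(y, x)$rmsd
  for (rep in 1:5) {
    tr <- random_rigid()
    y2 <- sweep(y %*% t(tr$R), 2L, tr$t, "+")
    expect_equal(kabsch_superpose(y2, x)$rmsd, base, tolerance = 1e-8)
    x2 <- sweep(x %*% t(tr$R), 2L, tr$t, "+")
    expect_equal(kabsch_superpose(y, x2)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("kabsch rejects degenerate selections", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  x <- matrix(rnorm(15), 5, 3)
  expect_error(kabsch_superpose(x, x, selection = 1:2), "at least 3")
})

test_that("backbone_rmsd_series: rigid motions give zero, jitter matches
           the closed-form expectation", {
  spec <- synthetic_spec(seed = 21, n_frames = 200, jitter_sigma = 0.2)
  cx <- build_toy_complex(spec)
  top <- cx$topology
  sel <- which(top$atoms$partition == "receptor" &
                 top$atoms$element != "H")
  # frames that are rigid motions of the base: all rmsd 0
  set.seed(5)
  rigid <- lapply(1:4, function(k) {
    tr <- random_rigid()
    sweep(cx$base %*% t(tr$R), 2L, tr$t, "+")
  })
  rs0 <- backbone_rmsd_series(ensemble(top, rigid), cx$base, sel)
  expect_equal(max(rs0$rmsd), 0, tolerance = 1e-8)

  ens <- generate_ensemble(cx, spec)$ensemble
  rs <- backbone_rmsd_series(ens, cx$base, sel)
  # E[rmsd] for iid Gaussian jitter after removing 6 rigid dof:
  # rmsd^2 ~ sigma^2 chi^2_{3M-6} / M
  M <- length(sel); k <- 3 * M - 6
  expected <- spec$jitter_sigma / sqrt(M) * sqrt(2) *
    exp(lgamma((k + 1) / 2) - lgamma(k / 2))
  se <- stats::sd(rs$rmsd) / sqrt(length(rs$rmsd))
  expect_lt(abs(mean(rs$rmsd) - expected), 3 * se)
  # single frame equal to reference
  one <- backbone_rmsd_series(ensemble(top, list(cx$base)), cx$base, sel)
  expect_equal(one$rmsd, 0)
  expect_equal(one$summary$sample_std, 0)
})

test_that("rmsf_per_residue matches two-point and Gaussian oracles", {
  top <- topology(make_atoms(9L, resnum = rep(1:3, each = 3L)))
  base <- matrix(rnorm(27, sd = 4), 9, 3)
  # identical frames: zero everywhere
  same <- rmsf_per_residue(ensemble(top, list(base, base, base)))
  expect_equal(same$rmsf, rep(0, 3), tolerance = 1e-10)
  # two frames, one atom displaced by d: rmsf of that atom = d/2 (fit over
  # the unmoved atoms so superposition does not drag the displaced one)
  f2 <- base; f2[5L, ] <- f2[5L, ] + c(0.8, 0, 0)
  two <- rmsf_per_residue(ensemble(top, list(base, f2)), selection = 4:6,
                          fit_selection = c(1:4, 6:9))
  expect_equal(attr(two, "atom_rmsf")[2L], 0.4, tolerance = 1e-8)
  # one atom jittered isotropically: its RMSF approaches sigma * sqrt(3)
  set.seed(31)
  nfr <- 400
  frames <- lapply(seq_len(nfr), function(k) {
    fr <- base
    fr[5L, ] <- fr[5L, ] + rnorm(3, sd = 0.5)
    fr
  })
  r <- rmsf_per_residue(ensemble(top, frames), selection = 1:9,
                        fit_selection = c(1:4, 6:9))
  atom <- attr(r, "atom_rmsf")
  expect_equal(atom[-5L], rep(0, 8), tolerance = 1e-10)
  # sigma * sqrt(3), population-normalized; 3-SE band
  expect_lt(abs(atom[5L] - 0.5 * sqrt(3)), 3 * 0.5 * sqrt(3) /
              sqrt(2 * nfr))
  expect_error(rmsf_per_residue(ensemble(top, list(base))), "2 frames")
})

test_that("perceive_rings agrees with the brute-force cycle census", {
  # benzene: exactly one 6-ring
  benz <- topology(make_atoms(6L), bonds = cbind(1:6, c(2:6, 1L)))
  ref <- hexagon_coords()
  rings <- perceive_rings(benz, ref)
  expect_length(rings, 1L)
  expect_setequal(rings[[1L]]$member_atoms, 1:6)
  # naphthalene-like fused bicyclic: two 6-rings, not the 10-envelope
  bonds <- rbind(cbind(1:5, 2:6), c(6L, 1L), c(1L, 7L),
                 cbind(7:9, 8:10), c(10L, 6L))
  nap <- topology(make_atoms(10L), bonds = bonds)
  # coordinates: two fused planar hexagons sharing edge 1-6
  ang <- pi / 3 * (0:5)
  ringA <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  shared <- ringA[c(1L, 6L), ]
  centreB <- colMeans(shared) + c(1.2, -0.7, 0) * 1.4
  ringB <- sweep(cbind(1.4 * cos(ang + 0.5), 1.4 * sin(ang + 0.5), 0),
                 2L, centreB, "+")
  coords <- rbind(ringA, ringB[1:4, ])
  rings2 <- perceive_rings(nap, coords, planarity_tol = 10)
  oracle <- brute_force_cycles(nap$bonds, 10L, sizes = 5:6)
  expect_length(rings2, length(oracle))
  key <- function(m) paste(sort(m), collapse = "-")
  expect_setequal(vapply(oracle, key, character(1)),
                  vapply(rings2, function(r) key(r$member_atoms),
                         character(1)))
  expect_true(all(vapply(rings2, function(r)
    length(r$member_atoms), integer(1)) == 6L))
})

test_that("planarity filter excludes bent rings; explicit rings override", {
  benz <- topology(make_atoms(6L), bonds = cbind(1:6, c(2:6, 1L)))
  bent <- hexagon_coords()
  bent[1L, 3L] <- 1.0   # pushed far out of plane
  expect_length(perceive_rings(benz, bent, planarity_tol = 0.15), 0L)
  override <- topology(make_atoms(6L), bonds = cbind(1:6, c(2:6, 1L)),
                       rings = list(1:6))
  expect_length(perceive_rings(override, bent, planarity_tol = 10), 1L)
})

test_that("ring_pair_geometry matches constructed geometries", {
  a <- hexagon_coords(c(0, 0, 0))
  # coplanar-parallel offset 4 A along the normal
  b <- hexagon_coords(c(0, 0, 4))
  fr <- rbind(a, b)
  g <- ring_pair_geometry(fr, 1:6, 7:12)
  expect_equal(g$centroid_distance, 4, tolerance = 1e-10)
  expect_equal(g$interplane_angle, 0, tolerance = 1e-6)
  # perpendicular planes, centroids 5 A apart
  b2 <- hexagon_coords(c(5, 0, 0), rotation_about(c(1, 0, 0), 90))
  g2 <- ring_pair_geometry(rbind(a, b2), 1:6, 7:12)
  expect_equal(g2$centroid_distance, 5, tolerance = 1e-10)
  expect_equal(g2$interplane_angle, 90, tolerance = 1e-6)
  # explicit 31-degree tilt built by rotation matrix
  b3 <- hexagon_coords(c(2, 1, 4.5), rotation_about(c(0, 1, 0), 31))
  g3 <- ring_pair_geometry(rbind(a, b3), 1:6, 7:12)
  expect_equal(g3$interplane_angle, 31, tolerance = 1e-6)
  # symmetry under swapping, and folding of antiparallel normals
  g3r <- ring_pair_geometry(rbind(a, b3), 7:12, 1:6)
  expect_equal(g3, g3r)
  b4 <- hexagon_coords(c(0, 0, 4), rotation_about(c(1, 0, 0), 180))
  expect_equal(ring_pair_geometry(rbind(a, b4), 1:6,
                                  7:12)$interplane_angle,
               0, tolerance = 1e-6)
  expect_error(ring_pair_geometry(cbind(1:12, 0, 0), 1:6, 7:12),
               "collinear")
})

test_that("classify_stacking uses the documented thresholds", {
  expect_equal(classify_stacking(16), "parallel")
  expect_equal(classify_stacking(58), "tilted")
  expect_equal(classify_stacking(90), "perpendicular")
  expect_equal(classify_stacking(c(0, 30, 60, 89.9)),
               c("parallel", "tilted", "tilted", "perpendicular"))
  expect_error(classify_stacking(91), "outside")
  expect_error(classify_stacking(-1), "outside")
})

test_that("detect_stacking honours the strict 7 A criterion", {
  top <- two_ring_topology()
  mk <- function(d) rbind(hexagon_coords(), hexagon_coords(c(0, 0, d)))
  for (d in c(6.99, 7.01)) {
    ens <- ensemble(top, replicate(5, mk(d), simplify = FALSE))
    st <- detect_stacking(ens)
    if (d < 7) {
      expect_equal(st$summaries$occupancy, 1)
      expect_equal(nrow(st$records), 5L)
      expect_equal(st$summaries$dist_mean, d, tolerance = 1e-10)
    } else {
      expect_equal(st$summaries$occupancy, 0)
      expect_equal(nrow(st$records), 0L)
      # all-frame averaging mode still reports the geometry
      expect_equal(st$summaries$dist_mean_all, d, tolerance = 1e-10)
    }
  }
})

test_that("detect_stacking recovers synthetic ground truth", {
  spec <- synthetic_spec(seed = 7, n_frames = 200, jitter_sigma = 0.2)
  cx <- build_toy_complex(spec)
  gen <- generate_ensemble(cx, spec)
  st <- detect_stacking(gen$ensemble)
  s <- st$summaries[st$summaries$ring_a == 1 & st$summaries$ring_b == 3, ]
  expect_equal(s$occupancy, 1)
  se_d <- s$dist_std / sqrt(s$n_qualifying)
  se_a <- s$angle_std / sqrt(s$n_qualifying)
  expect_lt(abs(s$dist_mean - 5.07), 3 * se_d)
  expect_lt(abs(s$angle_mean - 40), 3 * se_a)
  # the manifest per-frame truth is what the detector saw
  truth <- gen$manifest$ring_truth[[1L]]
  expect_equal(st$records[st$records$ring_a == 1 & st$records$ring_b == 3,
                          "centroid_distance"],
               truth$centroid_distance, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("close_contact_fraction counts constructed contacts", {
  # receptor residue at varying distance from a 1-atom ligand
  at <- rbind(make_atoms(2L, resnum = 1L, partition = "receptor"),
              make_atoms(1L, resnum = 101L, partition = "ligand1"))
  at$serial <- 1:3
  top <- topology(at)
  mk <- function(d) rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 0, d))
  # within 5 A in exactly 7 of 10 frames
  ens <- ensemble(top, lapply(c(rep(4.2, 7), rep(6.0, 3)), mk))
  p <- close_contact_fraction(ens, "ligand1", 5.0)
  expect_s3_class(p, "contact_profile")
  expect_equal(p$contact_fraction, 0.7)
  # permanently >= 6 A: zero, but the residue is still reported
  far <- close_contact_fraction(ensemble(top, lapply(rep(6.5, 4), mk)),
                                "ligand1", 5.0)
  expect_equal(far$contact_fraction, 0)
  expect_error(close_contact_fraction(ens, "cofactor"), "empty")
})

test_that("contact fractions are monotone in the cutoff", {
  spec <- synthetic_spec(seed = 17, n_frames = 30, jitter_sigma = 0.3)
  cx <- build_toy_complex(spec)
  ens <- generate_ensemble(cx, spec)$ensemble
  p5 <- close_contact_fraction(ens, "ligand1", 5.0)
  p6 <- close_contact_fraction(ens, "ligand1", 6.0)
  expect_true(all(p6$contact_fraction >= p5$contact_fraction))
  # determinism: equal ensembles give identical profiles
  expect_identical(close_contact_fraction(ens, "ligand1", 5.0), p5)
})

test_that("hydrogen bonds: occupancy and distances on fixtures", {
  # donor D(1) - H(2), acceptor A(3)
  at <- make_atoms(3L, element = c("N", "H", "O"),
                   partition = c("receptor", "receptor", "ligand1"),
                   resnum = c(1L, 1L, 101L))
  top <- topology(at, bonds = cbind(1L, 2L))
  mk <- function(d) rbind(c(0, 0, 0), c(1, 0, 0), c(d, 0, 0))
  ens <- ensemble(top, replicate(4, mk(2.83), simplify = FALSE))
  hb <- hydrogen_bonds(ens, donors = 1L, acceptors = 3L)
  expect_equal(hb$occupancy, 1)
  expect_equal(hb$heavy_atom_distance, 2.83, tolerance = 1e-10)
  expect_equal(hb$donor_angle, 180, tolerance = 1e-6)
  # fixed at 3.8 A: never satisfied
  hb2 <- hydrogen_bonds(ensemble(top, replicate(3, mk(3.8),
                                                simplify = FALSE)),
                        1L, 3L)
  expect_equal(hb2$occupancy, 0)
  expect_true(is.na(hb2$heavy_atom_distance))
  # half the frames at 3.16, half at 4.5: occupancy 0.5
  ens3 <- ensemble(top, lapply(c(3.16, 3.16, 4.5, 4.5), mk))
  hb3 <- hydrogen_bonds(ens3, 1L, 3L)
  expect_equal(hb3$occupancy, 0.5)
  expect_equal(hb3$heavy_atom_distance, 3.16, tolerance = 1e-10)
  # angle screening: bent arrangement fails the 120-degree cut
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2.5, 0))
  hb4 <- hydrogen_bonds(ensemble(top, list(bent)), 1L, 3L)
  expect_equal(hb4$occupancy, 0)
  hb5 <- hydrogen_bonds(ensemble(top, list(bent)), 1L, 3L,
                        check_angle = FALSE)
  expect_equal(hb5$occupancy, 1)
  # donor without a bonded hydrogen errors in angle mode
  expect_error(hydrogen_bonds(ens, donors = 3L, acceptors = 1L),
               "no bonded hydrogen")
})

test_that("distance_series summarizes per-frame distances", {
  top <- topology(make_atoms(2L))
  mk <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  ds <- distance_series(ensemble(top, replicate(6, mk(5.24),
                                                simplify = FALSE)), 1L, 2L)
  expect_equal(ds$summary$mean, 5.24, tolerance = 1e-12)
  expect_equal(ds$summary$sample_std, 0)
  ds2 <- distance_series(ensemble(top, lapply(c(3, 5), mk)), 1L, 2L)
  expect_equal(ds2$summary$mean, 4)
  expect_equal(ds2$summary$sample_std, sqrt(2), tolerance = 1e-12)
  expect_error(distance_series(ensemble(top, list(mk(3))), 2L, 2L),
               "identical")
})
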