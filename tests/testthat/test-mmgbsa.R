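# single-trajectory MM-GB/SA, decomposition, permutation comparison

test_that("toy host-guest frame matches a fully hand-enumerated oracle", {
  top <- host_guest_topology()
  fr <- host_guest_frame()
  p <- solvent_params()
  ens <- ensemble(top, list(fr))
  b <- single_trajectory_mmgbsa(ens, p, "GB")
  idx_c <- 1:4; idx_r <- 1:3; idx_l <- 4L
  # gas terms: independent naive loops per species
  dE_ele <- naive_coulomb(fr, top, idx_c) - naive_coulomb(fr, top, idx_r) -
    naive_coulomb(fr, top, idx_l)
  dE_vdw <- naive_lj(fr, top, idx_c) - naive_lj(fr, top, idx_r) -
    naive_lj(fr, top, idx_l)
  # GB with per-species effective radii, via the naive double sum
  gb_naive <- function(sub) {
    radii <- effective_born_radii(fr, top, sub, p)
    naive_gb(fr, top, sub, radii)
  }
  dG_pol <- gb_naive(idx_c) - gb_naive(idx_r) - gb_naive(idx_l)
  dG_np <- p$gamma *
    (shrake_rupley_sasa(fr, top, idx_c, p)$total -
       shrake_rupley_sasa(fr, top, idx_r, p)$total -
       shrake_rupley_sasa(fr, top, idx_l, p)$total)
  s <- b$summary
  g <- function(term) s$mean[s$term == term]
  expect_equal(g("dE_ele"), dE_ele, tolerance = 1e-8)
  expect_equal(g("dE_vdw"), dE_vdw, tolerance = 1e-8)
  expect_equal(g("dG_nonpolar"), dG_np, tolerance = 1e-8)
  expect_equal(g("dG_sol"), dG_pol + dG_np, tolerance = 1e-8)
  expect_equal(g("dG_bind"), dE_ele + dE_vdw + dG_pol + dG_np,
               tolerance = 1e-8)
  expect_equal(g("dG_ele_total"), dE_ele + dG_pol, tolerance = 1e-8)
})

test_that("bookkeeping identities hold per frame", {
  spec <- synthetic_spec(seed = 8, n_frames = 6, jitter_sigma = 0.15)
  cx <- build_toy_complex(spec)
  ens <- generate_ensemble(cx, spec)$ensemble
  b <- single_trajectory_mmgbsa(ens, solvent_params(), "GB")
  s <- b$series
  expect_equal(s$dE_gas, s$dE_ele + s$dE_vdw, tolerance = 1e-12)
  expect_equal(s$dG_bind, s$dE_gas + s$dG_sol, tolerance = 1e-12)
  expect_equal(s$dG_ele_total, s$dE_ele + s$dG_sol - s$dG_nonpolar,
               tolerance = 1e-12)
  expect_equal(b$summary$n_frames, rep(6L, 7L))
})

test_that("non-interacting ligand gives vanishing binding energy (GB)", {
  at <- rbind(make_atoms(3L, charge = c(0.3, -0.2, -0.1),
                         partition = "receptor"),
              make_atoms(2L, charge = c(0.4, -0.4),
                         partition = "ligand1", resnum = 101L))
  at$serial <- 1:5
  top <- topology(at, bonds = rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L)))
  fr <- rbind(c(0, 0, 0), c(1.6, 0, 0), c(0.8, 1.4, 0),
              c(500, 0, 0), c(501.5, 0, 0))
  b <- single_trajectory_mmgbsa(ensemble(top, list(fr)), solvent_params(),
                                "GB")
  s <- b$summary
  for (term in c("dE_ele", "dE_vdw", "dG_bind"))
    expect_lt(abs(s$mean[s$term == term]), 1e-3)
})

test_that("PB and GB paths run through the same bookkeeping", {
  top <- host_guest_topology()
  ens <- ensemble(top, list(host_guest_frame()))
  p <- solvent_params(pb_grid_spacing = 0.6, pb_padding = 6)
  b <- single_trajectory_mmgbsa(ens, p, "PB")
  expect_equal(b$solvent_model, "PB")
  s <- b$series
  expect_equal(s$dG_bind, s$dE_gas + s$dG_sol, tolerance = 1e-12)
  # polar desolvation penalty opposes binding in both models
  bg <- single_trajectory_mmgbsa(ens, p, "GB")
  dpol_pb <- s$dG_sol - s$dG_nonpolar
  dpol_gb <- bg$series$dG_sol - bg$series$dG_nonpolar
  expect_gt(dpol_pb, 0)
  expect_gt(dpol_gb, 0)
})

test_that("per-residue decomposition conserves the total and is fair", {
  spec <- synthetic_spec(seed = 14, n_frames = 4, jitter_sigma = 0.1)
  cx <- build_toy_complex(spec)
  ens <- generate_ensemble(cx, spec)$ensemble
  p <- solvent_params()
  b <- single_trajectory_mmgbsa(ens, p, "GB")
  dec <- per_residue_decomposition(ens, p)
  fm <- attr(dec, "frame_matrix")
  expect_equal(rowSums(fm), b$series$dG_bind, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(per_residue_decomposition(ens, p, solvent_model = "PB"),
               "unsupported|pairwise")
})

test_that("single receptor residue absorbs the whole binding energy", {
  top <- host_guest_topology()   # one receptor residue + one ligand atom
  ens <- ensemble(top, list(host_guest_frame()))
  p <- solvent_params()
  b <- single_trajectory_mmgbsa(ens, p, "GB")
  dec <- per_residue_decomposition(ens, p)
  expect_setequal(dec$residue, c("1", "LIG"))
  expect_equal(sum(dec$mean), b$summary$mean[b$summary$term == "dG_bind"],
               tolerance = 1e-8)
})

test_that("symmetric residues get equal contributions", {
  # two identical 1-atom residues mirrored about a central ligand atom
  at <- rbind(make_atoms(2L, charge = 0.2, resnum = c(1L, 2L),
                         partition = "receptor"),
              make_atoms(1L, charge = -0.4, resnum = 101L,
                         partition = "ligand1"))
  at$serial <- 1:3
  top <- topology(at)
  fr <- rbind(c(-4, 0, 0), c(4, 0, 0), c(0, 0, 0))
  # gas + GB terms are analytically mirror-symmetric; run them alone
  # (gamma = 0) for the tight comparison
  dec <- per_residue_decomposition(ensemble(top, list(fr)),
                                   solvent_params(gamma = 0))
  r1 <- dec$mean[dec$residue == "1"]
  r2 <- dec$mean[dec$residue == "2"]
  expect_equal(r1, r2, tolerance = 1e-8)
  # the point-sampled SASA term is symmetric only to quadrature accuracy
  dec2 <- per_residue_decomposition(ensemble(top, list(fr)),
                                    solvent_params())
  expect_equal(dec2$mean[dec2$residue == "1"],
               dec2$mean[dec2$residue == "2"], tolerance = 0.02)
})

test_that("decomposition ranking matches a brute-force re-accumulation", {
  spec <- synthetic_spec(seed = 19, n_frames = 2, jitter_sigma = 0.1)
  cx <- build_toy_complex(spec)
  ens <- generate_ensemble(cx, spec)$ensemble
  top <- ens$topology
  p <- solvent_params()
  dec <- per_residue_decomposition(ens, p)
  # oracle: gas-phase cross-pair energies re-accumulated per residue with
  # plain loops (the dominant, unambiguous part of the split)
  lig <- which(top$atoms$partition == "ligand1")
  rec <- which(top$atoms$partition == "receptor")
  gas_oracle <- setNames(numeric(length(unique(top$atoms$resnum[rec]))),
                         sort(unique(top$atoms$resnum[rec])))
  fr <- ens$frames[[1L]]
  at <- top$atoms
  for (i in lig) for (j in rec) {
    r <- sqrt(sum((fr[i, ] - fr[j, ])^2))
    e <- 332.0637 * at$charge[i] * at$charge[j] / r
    rmin <- at$rmin_half[i] + at$rmin_half[j]
    eps <- sqrt(at$epsilon[i] * at$epsilon[j])
    e <- e + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    key <- as.character(at$resnum[j])
    gas_oracle[key] <- gas_oracle[key] + e / 2
  }
  fm <- attr(dec, "frame_matrix")[1L, ]
  fm <- fm[names(fm) != "LIG"]
  # solvation redistributes magnitude but the gas-dominated ranking of the
  # strongly interacting residues must survive
  top3 <- names(sort(gas_oracle))[1:3]
  expect_setequal(names(sort(fm))[1:3], top3)
})

test_that("compare_breakdowns: permutation test behaves at the extremes", {
  set.seed(3)
  x <- rnorm(30)
  same <- compare_breakdowns(x, x, n_resamples = 199, seed = 42)
  expect_equal(same$ddG, 0)
  expect_equal(same$p_value, 1)
  apart <- compare_breakdowns(x, x + 10 * sd(x), n_resamples = 199,
                              seed = 42)
  expect_equal(apart$ddG, 10 * sd(x))
  expect_lte(apart$p_value, 1 / 200)
  expect_error(compare_breakdowns(x[1L], x, 99, seed = 1), "2 frames")
  expect_error(compare_breakdowns(x, x, 99), "seed")
  # deterministic under the seed
  a <- compare_breakdowns(x, x + 0.3, 199, seed = 7)
  b <- compare_breakdowns(x, x + 0.3, 199, seed = 7)
  expect_identical(a, b)
})
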