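#' @title Synthetic toy complexes and ensembles
#' @name synthetic_ensembles
#' @description
#' Generates miniature receptor-ligand complexes with known ground truth so
#' every analysis stage can be validated without molecular dynamics data.
#' The receptor is a ring of template residues around a pocket: aromatic
#' six-ring side-chain analogues, one amine-like hydrogen-bond donor
#' analogue, and aliphatic spacers. Each ligand carries two planar six-rings
#' joined by a short linker plus a carbonyl-like acceptor oxygen (echoing a
#' two-ring azole drug). Ring placements satisfy the requested stacking
#' geometry (centroid distance, inter-plane angle) exactly in the base
#' frame; ensembles add i.i.d. isotropic Gaussian jitter per atom and an
#' optional per-molecule rigid random-walk drift. The jitter is a
#' statistical stand-in for thermal fluctuation, not a physical model:
#' it has no covariance structure, no bonded constraints and no Boltzmann
#' weighting.
NULL

# built-in template parameter table (charges in e, radii in Angstrom,
# epsilon in kcal/mol); values in conventional force-field ranges
SYNTH_ATOM_TYPES <- data.frame(
  type = c("CA", "CT", "N", "HN", "O", "CO"),
  element = c("C", "C", "N", "H", "O", "C"),
  rmin_half = c(1.908, 1.908, 1.824, 0.600, 1.661, 1.908),
  epsilon = c(0.0860, 0.1094, 0.1700, 0.0157, 0.2100, 0.0860),
  born_radius = c(1.70, 1.70, 1.55, 1.20, 1.50, 1.70),
  q_polar = c(0.00, 0.00, -0.60, 0.40, -0.50, 0.50),
  stringsAsFactors = FALSE)

#' Specification of a synthetic study arm
#'
#' Defaults state the emulated world: 200 frames with 0.2 Angstrom thermal
#' jitter, a 6-residue pocket with 2 aromatic analogues, one ligand whose
#' first ring stacks on the first aromatic residue at 5.07 Angstrom and
#' 40 degrees (a typical parallel-displaced aromatic pair in a CYP-like
#' pocket), a 2.9 Angstrom donor-acceptor hydrogen bond, and polar-pair
#' charges so the designed interaction is net attractive.
#'
#' @param seed RNG seed (Mersenne-Twister via `set.seed`).
#' @param n_frames number of frames (>= 1).
#' @param jitter_sigma per-coordinate Gaussian jitter, Angstrom (>= 0).
#' @param receptor_n_residues pocket size, 4-30 residues.
#' @param n_aromatic_residues number of aromatic analogues (>= 1).
#' @param n_ligands 1 or 2.
#' @param stacking_targets list of `list(ligand =, receptor_ring =,
#'   distance =, angle =)`; at most one per ligand copy (it fixes the
#'   copy's rigid placement). Defaults place ligand 1 at
#'   (5.07 Angstrom, 40 deg) on aromatic residue 1, and ligand 2 (when
#'   present) at (4.5 Angstrom, 10 deg) over ligand 1's second ring.
#' @param charge_scheme "polar-pairs" or "neutral" (all charges zero).
#' @param drift per-frame rigid-body random-walk step, Angstrom (0 = off).
#' @param hbond_length designed donor-acceptor distance, Angstrom.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_frames = 200L, jitter_sigma = 0.2,
                           receptor_n_residues = 6L,
                           n_aromatic_residues = 2L,
                           n_ligands = 1L,
                           stacking_targets = NULL,
                           charge_scheme = c("polar-pairs", "neutral"),
                           drift = 0,
                           hbond_length = 2.9) {
  charge_scheme <- match.arg(charge_scheme)
  stopifnot(n_frames >= 1L, jitter_sigma >= 0,
            receptor_n_residues >= 4L, receptor_n_residues <= 30L,
            n_aromatic_residues >= 1L,
            n_aromatic_residues <= receptor_n_residues - 1L,
            n_ligands %in% 1:2, drift >= 0, hbond_length > 0)
  if (is.null(stacking_targets))
    stacking_targets <- list(list(ligand = 1L, receptor_ring = 1L,
                                  distance = 5.07, angle = 40))
  lig_ids <- vapply(stacking_targets, function(t) as.integer(t$ligand),
                    integer(1))
  if (anyDuplicated(lig_ids))
    stop("synthetic_spec: at most one stacking target per ligand copy")
  for (t in stacking_targets)
    stopifnot(t$distance > 0, t$angle >= 0, t$angle <= 90,
              t$receptor_ring >= 1, t$receptor_ring <= n_aromatic_residues)
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 jitter_sigma = jitter_sigma,
                 receptor_n_residues = as.integer(receptor_n_residues),
                 n_aromatic_residues = as.integer(n_aromatic_residues),
                 n_ligands = as.integer(n_ligands),
                 stacking_targets = stacking_targets,
                 charge_scheme = charge_scheme,
                 drift = drift, hbond_length = hbond_length),
            class = "synthetic_spec")
}

hexagon <- function(radius = 1.4) {
  ang <- (0:5) * pi / 3
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), sin(th),
           0, -sin(th), cos(th)), 3L, 3L)
}

# local ligand: ring A (atoms 1-6, centroid at origin, xy plane), linker
# CT-CT with an acceptor O on the first linker carbon, ring B (centroid
# (6.8,0,0))
ligand_template <- function() {
  ringA <- hexagon()
  ct1 <- c(2.9, 0, 0); o <- c(3.4, 1.2, 0); ct2 <- c(4.0, -0.8, 0)
  ringB <- sweep(hexagon(), 2L, c(6.8, 0, 0), "+")
  coords <- rbind(ringA, ct1, o, ct2, ringB)
  types <- c(rep("CA", 6L), "CO", "O", "CT", rep("CA", 6L))
  names <- c(paste0("C", 1:6), "C7", "O1", "C8", paste0("C", 9:14))
  bonds <- rbind(cbind(1:6, c(2:6, 1L)),       # ring A
                 c(1L, 7L), c(7L, 8L), c(7L, 9L), c(9L, 10L),
                 cbind(10:15, c(11:15, 10L)))  # ring B
  list(coords = coords, types = types, names = names, bonds = bonds,
       ringA = 1:6, ringB = 10:15, acceptor = 8L)
}

#' Build the base frame and topology of a toy complex
#'
#' Receptor residues sit on a circle of radius 8 Angstrom in the z = 0
#' plane (aromatic rings lying in-plane, so their normals are +z); each
#' ligand is placed rigidly so that its first ring meets its stacking
#' target exactly (centroid at the target distance along the partner ring
#' normal, plane tilted by the target angle). The donor-analogue residue is
#' positioned so its nitrogen sits at `hbond_length` from ligand 1's
#' acceptor oxygen with the N-H pointing straight at it. A steric check
#' rejects specs that bring non-bonded atoms below 1.5 Angstrom.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `topology` and `base` (the base-frame coordinates).
#' @export
build_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_rec <- spec$receptor_n_residues
  n_aro <- spec$n_aromatic_residues
  pocket_radius <- 8
  site_angle <- 2 * pi * (seq_len(n_rec) - 1L) / n_rec
  sites <- cbind(pocket_radius * cos(site_angle),
                 pocket_radius * sin(site_angle), 0)

  atoms <- list(); coords <- list(); bonds <- list(); offset <- 0L
  add_res <- function(xyz, types, names, resnum, resname, chain, partition,
                      local_bonds) {
    serial0 <- offset
    tt <- SYNTH_ATOM_TYPES[match(types, SYNTH_ATOM_TYPES$type), ]
    q <- if (spec$charge_scheme == "polar-pairs") tt$q_polar else 0
    atoms[[length(atoms) + 1L]] <<- data.frame(
      serial = serial0 + seq_len(nrow(xyz)), name = names,
      element = tt$element, resnum = resnum, resname = resname,
      chain = chain, charge = q, rmin_half = tt$rmin_half,
      epsilon = tt$epsilon, born_radius = tt$born_radius,
      partition = partition, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
    if (NROW(local_bonds))
      bonds[[length(bonds) + 1L]] <<- local_bonds + serial0
    offset <<- offset + nrow(xyz)
  }

  aro_ring_atoms <- list()
  # aromatic analogues occupy the first n_aro sites
  for (r in seq_len(n_aro)) {
    ring <- sweep(hexagon(), 2L, sites[r, ], "+")
    add_res(ring, rep("CA", 6L), paste0("CZ", 1:6), r, "ARO", "A",
            "receptor", cbind(1:6, c(2:6, 1L)))
    aro_ring_atoms[[r]] <- offset - 6L + 1:6
  }
  # aliphatic spacers on the remaining sites except the last (donor's slot)
  for (r in seq(n_aro + 1L, n_rec - 1L, length.out =
                  max(0L, n_rec - 1L - n_aro))) {
    tang <- c(-sin(site_angle[r]), cos(site_angle[r]), 0)
    chain <- rbind(sites[r, ], sites[r, ] + 1.5 * tang,
                   sites[r, ] + 3.0 * tang)
    add_res(chain, rep("CT", 3L), c("CB", "CG", "CD"), r, "ALA", "A",
            "receptor", rbind(c(1L, 2L), c(2L, 3L)))
  }

  # ligands, placed by their stacking targets
  tmpl <- ligand_template()
  lig_info <- list()
  targets <- spec$stacking_targets
  target_for <- function(k) {
    for (t in targets) if (t$ligand == k) return(t)
    NULL
  }
  for (k in seq_len(spec$n_ligands)) {
    t <- target_for(k)
    if (k == 1L && is.null(t))
      t <- list(ligand = 1L, receptor_ring = 1L, distance = 5.07,
                angle = 40)
    if (is.null(t)) {
      # default second-copy placement: over ligand 1's second ring
      anchor_centroid <- colMeans(
        lig_info[[1L]]$coords[tmpl$ringB, , drop = FALSE])
      anchor_normal <- lig_info[[1L]]$normal
      dist <- 4.5; ang <- 10 + lig_info[[1L]]$tilt
    } else {
      anchor_centroid <- sites[t$receptor_ring, ]
      anchor_normal <- c(0, 0, 1)
      dist <- t$distance; ang <- t$angle
    }
    R <- rot_x(ang)
    xyz <- tmpl$coords %*% R
    xyz <- sweep(xyz, 2L, anchor_centroid + dist * anchor_normal, "+")
    add_res(xyz, tmpl$types, tmpl$names, 100L + k, "LIG",
            c("B", "C")[k], paste0("ligand", k), tmpl$bonds)
    lig_info[[k]] <- list(
      coords = xyz,
      atoms = offset - nrow(xyz) + seq_len(nrow(xyz)),
      normal = as.numeric(c(0, 0, 1) %*% R),
      tilt = ang)
  }

  # donor analogue aimed at ligand 1's acceptor oxygen, on the last site's
  # residue number
  o_idx_local <- tmpl$acceptor
  o_pos <- lig_info[[1L]]$coords[o_idx_local, ]
  c7 <- lig_info[[1L]]$coords[7L, ]
  u <- o_pos - c7; u <- u / sqrt(sum(u^2))
  n_pos <- o_pos + spec$hbond_length * u
  h_pos <- n_pos - 1.0 * u
  ct_pos <- n_pos + 1.5 * u
  add_res(rbind(ct_pos, n_pos, h_pos), c("CT", "N", "HN"),
          c("CB", "ND", "HD"), n_rec, "DON", "A", "receptor",
          rbind(c(1L, 2L), c(2L, 3L)))

  atoms <- do.call(rbind, atoms)
  base <- do.call(rbind, coords)
  dimnames(base) <- NULL
  bonds <- do.call(rbind, bonds)
  # explicit ring definitions: perception must not depend on how much
  # thermal jitter a frame carries
  ring_defs <- c(aro_ring_atoms,
                 unlist(lapply(lig_info, function(li)
                   list(li$atoms[tmpl$ringA], li$atoms[tmpl$ringB])),
                   recursive = FALSE))
  top <- topology(atoms, bonds = bonds, rings = ring_defs)

  # steric feasibility: non-bonded atoms may not overlap below 1.5 A
  d <- as.matrix(stats::dist(base))
  diag(d) <- Inf
  for (b in seq_len(nrow(top$bonds)))
    d[top$bonds[b, 1L], top$bonds[b, 2L]] <-
      d[top$bonds[b, 2L], top$bonds[b, 1L]] <- Inf
  # neighbours within a ring/residue are bonded or 1-3; exempt 1-3 too
  for (e in seq_len(nrow(top$exclusions)))
    d[top$exclusions[e, 1L], top$exclusions[e, 2L]] <-
      d[top$exclusions[e, 2L], top$exclusions[e, 1L]] <- Inf
  if (min(d) < 1.5)
    stop(sprintf(paste0("build_toy_complex: infeasible stacking targets ",
                        "(non-bonded atoms %d and %d at %.2f Angstrom)"),
                 which(d == min(d), arr.ind = TRUE)[1L, 1L],
                 which(d == min(d), arr.ind = TRUE)[1L, 2L], min(d)))

  donor_n <- offset - 1L  # the N of the donor residue (second-to-last atom)
  list(topology = top, base = base,
       ligand_rings = lapply(lig_info, function(li)
         list(ringA = li$atoms[tmpl$ringA], ringB = li$atoms[tmpl$ringB])),
       receptor_rings = aro_ring_atoms,
       donor_atom = donor_n,
       acceptor_atom = lig_info[[1L]]$atoms[o_idx_local])
}

#' Generate a jittered ensemble plus its ground-truth manifest
#'
#' Frames are `base + N(0, sigma^2)` i.i.d. per coordinate (Mersenne-
#' Twister, seeded from the spec), plus an optional per-molecule rigid
#' translation performing a Gaussian random walk of step `drift`. The
#' manifest records, per frame, the true stacking geometry of every
#' designed ring pair (computed from the jittered coordinates), per-residue
#' contact indicators at 5 Angstrom, the designed hydrogen-bond pair, and
#' the designed interaction sign.
#'
#' @param complex output of [build_toy_complex()] (topology + base frame).
#' @param spec the [synthetic_spec()] used to build it.
#' @return list with `ensemble` and `manifest`.
#' @export
generate_ensemble <- function(complex, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  top <- complex$topology
  base <- complex$base
  n <- nrow(base)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  mols <- split(seq_len(n), top$atoms$partition[seq_len(n)])
  frames <- vector("list", spec$n_frames)
  drift_state <- lapply(mols, function(m) c(0, 0, 0))
  for (k in seq_len(spec$n_frames)) {
    fr <- base + matrix(stats::rnorm(3L * n, sd = spec$jitter_sigma), n, 3L)
    if (spec$drift > 0) {
      for (mi in seq_along(mols)) {
        drift_state[[mi]] <- drift_state[[mi]] +
          stats::rnorm(3L, sd = spec$drift)
        fr[mols[[mi]], ] <- sweep(fr[mols[[mi]], , drop = FALSE], 2L,
                                  drift_state[[mi]], "+")
      }
    }
    frames[[k]] <- fr
  }
  ens <- ensemble(top, frames)

  # designed ring pairs: (receptor ring or ligand-1 ring B) vs ligand ring A
  pair_defs <- list()
  for (t in spec$stacking_targets) {
    pair_defs[[length(pair_defs) + 1L]] <- list(
      label = sprintf("receptor_ring%d-ligand%d_ringA", t$receptor_ring,
                      t$ligand),
      a = complex$receptor_rings[[t$receptor_ring]],
      b = complex$ligand_rings[[t$ligand]]$ringA,
      target_distance = t$distance, target_angle = t$angle)
  }
  ring_truth <- lapply(pair_defs, function(pd) {
    geo <- t(vapply(frames, function(fr) {
      g <- ring_pair_geometry(fr, pd$a, pd$b)
      c(g$centroid_distance, g$interplane_angle)
    }, numeric(2)))
    data.frame(frame = seq_len(spec$n_frames),
               centroid_distance = geo[, 1L],
               interplane_angle = geo[, 2L])
  })
  names(ring_truth) <- vapply(pair_defs, `[[`, character(1), "label")

  heavy <- toupper(top$atoms$element) != "H"
  lig1 <- intersect(partition_indices(top, "ligand1"), which(heavy))
  rec_atoms <- split(intersect(which(top$atoms$partition == "receptor"),
                               which(heavy)),
                     top$atoms$resnum[top$atoms$partition == "receptor" &
                                        heavy])
  contact_truth <- t(vapply(frames, function(fr) {
    L <- fr[lig1, , drop = FALSE]
    vapply(rec_atoms, function(ix) {
      R <- fr[ix, , drop = FALSE]
      d2 <- outer(rowSums(R^2), rowSums(L^2), "+") - 2 * tcrossprod(R, L)
      min(d2) < 25
    }, logical(1))
  }, logical(length(rec_atoms))))

  manifest <- list(
    seed = spec$seed, rng = "Mersenne-Twister (base R set.seed)",
    n_frames = spec$n_frames, jitter_sigma = spec$jitter_sigma,
    drift = spec$drift, charge_scheme = spec$charge_scheme,
    stacking_targets = spec$stacking_targets,
    ring_pairs = lapply(pair_defs, function(pd)
      pd[c("label", "a", "b", "target_distance", "target_angle")]),
    ring_truth = ring_truth,
    contact_truth = contact_truth,
    hbond = list(donor_atom = complex$donor_atom,
                 acceptor_atom = complex$acceptor_atom,
                 target_length = spec$hbond_length),
    expected_interaction_sign =
      if (spec$charge_scheme == "polar-pairs") "attractive" else
        "vdw-attractive",
    partition_sizes = table(top$atoms$partition))
  list(ensemble = ens, manifest = manifest)
}

#' Build a paired normal / cooperative synthetic study
#'
#' Both arms must share the receptor template (residue counts and charge
#' scheme); the cooperative arm must carry two ligand copies. The manifest
#' records which arm was designed with the shorter ligand-1 stacking
#' distance, i.e. the designed stronger-binding arm.
#'
#' @param spec_normal,spec_cooperative [synthetic_spec()] objects.
#' @return list with `normal` and `cooperative` (each: `topology`, `base`,
#'   `ensemble`, `manifest`) and `designed_stronger_arm`.
#' @export
make_two_arm_study <- function(spec_normal, spec_cooperative) {
  same <- function(f) identical(spec_normal[[f]], spec_cooperative[[f]])
  if (!all(vapply(c("receptor_n_residues", "n_aromatic_residues",
                    "charge_scheme"), same, logical(1))))
    stop("make_two_arm_study: receptor templates differ between arms")
  if (spec_cooperative$n_ligands != 2L)
    stop("make_two_arm_study: cooperative arm must have n_ligands = 2")
  build <- function(spec) {
    cx <- build_toy_complex(spec)
    gen <- generate_ensemble(cx, spec)
    list(topology = cx$topology, base = cx$base, complex = cx,
         ensemble = gen$ensemble, manifest = gen$manifest)
  }
  arm_n <- build(spec_normal)
  arm_c <- build(spec_cooperative)
  d1 <- function(spec) {
    for (t in spec$stacking_targets) if (t$ligand == 1L) return(t$distance)
    5.07
  }
  stronger <- if (d1(spec_cooperative) < d1(spec_normal)) "cooperative"
    else if (d1(spec_cooperative) > d1(spec_normal)) "normal" else "equal"
  list(normal = arm_n, cooperative = arm_c,
       designed_stronger_arm = stronger)
}

#' Write a synthetic study arm to disk
#'
#' Emits `complex.pdb` (multi-model), `topology.json` and `manifest.json`
#' under `out_dir`.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_synthetic_arm <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cx <- build_toy_complex(spec)
  gen <- generate_ensemble(cx, spec)
  paths <- file.path(out_dir, c("complex.pdb", "topology.json",
                                "manifest.json"))
  write_ensemble(gen$ensemble, paths[1L])
  write_topology(cx$topology, paths[2L])
  man <- gen$manifest
  man$contact_truth <- NULL  # bulky; regenerate from the spec if needed
  jsonlite::write_json(man, paths[3L], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(paths)
}
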