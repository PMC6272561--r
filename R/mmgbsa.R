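#' @title End-state binding free energy estimation
#' @name mmgbsa
#' @description
#' Single-trajectory MM-PB/SA and MM-GB/SA: for every ensemble frame the
#' complex, receptor and ligand energies are evaluated on the same complex
#' geometry, so internal bonded terms (bond/angle/torsion) cancel
#' identically in the difference and only nonbonded gas terms and solvation
#' survive:
#' `dG_bind = dE_gas + dG_sol`, `dE_gas = dE_ele + dE_vdw`,
#' `dG_sol = dG_polar + dG_nonpolar`. Configurational entropy (-T dS) is
#' deliberately not computed (set to zero), as is conventional when
#' comparing binding modes of near-identical systems. The bookkeeping row
#' `dG_ele_total = dE_ele + (dG_sol - dG_nonpolar)` groups all
#' electrostatics (gas + polar solvation).
NULL

BREAKDOWN_TERMS <- c("dE_ele", "dE_vdw", "dE_gas", "dG_nonpolar",
                     "dG_sol", "dG_ele_total", "dG_bind")

# receptor-side atom set: everything that is not the ligand of interest,
# optionally dropping a second ligand copy entirely
mm_partitions <- function(top, ligand_partition = "ligand1",
                          include_second_ligand = TRUE) {
  lig <- partition_indices(top, ligand_partition)
  if (!length(lig))
    stop("partition '", ligand_partition, "' is empty")
  other <- setdiff(PARTITION_LABELS, ligand_partition)
  if (!include_second_ligand)
    other <- setdiff(other, c("ligand1", "ligand2")[
      c("ligand1", "ligand2") != ligand_partition])
  rec <- which(top$atoms$partition %in% other)
  if (!length(rec)) stop("receptor-side atom set is empty")
  list(ligand = lig, receptor = rec, complex = sort(c(lig, rec)))
}

#' Single-trajectory MM-PB/SA or MM-GB/SA binding free energy
#'
#' @param ens an `ensemble` of complex-phase frames.
#' @param params a [solvent_params()].
#' @param solvent_model "GB" (generalized Born) or "PB" (finite-difference
#'   Poisson-Boltzmann) for the polar solvation term.
#' @param ligand_partition the ligand of interest (default "ligand1").
#' @param include_second_ligand when a second ligand copy exists, treat it
#'   as part of the receptor (default TRUE, the "first ligand" convention
#'   in cooperative models); `FALSE` removes it from the system.
#' @param frames optional subset of frame indices to analyse.
#' @return an `energy_breakdown`: `solvent_model`, per-frame `series` for
#'   each term (kcal/mol), and `summary` data.frame (term, mean,
#'   sample_std, n_frames).
#' @export
single_trajectory_mmgbsa <- function(ens, params = solvent_params(),
                                     solvent_model = c("GB", "PB"),
                                     ligand_partition = "ligand1",
                                     include_second_ligand = TRUE,
                                     frames = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  solvent_model <- match.arg(solvent_model)
  top <- ens$topology
  sets <- mm_partitions(top, ligand_partition, include_second_ligand)
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  nf <- length(frames)
  series <- matrix(NA_real_, nf, length(BREAKDOWN_TERMS),
                   dimnames = list(NULL, BREAKDOWN_TERMS))
  polar_fun <- if (solvent_model == "GB") {
    function(fr, sub) gb_polar_energy(fr, top, sub, params)
  } else {
    function(fr, sub) fd_poisson_boltzmann(fr, top, sub, params)
  }
  for (k in seq_len(nf)) {
    fr <- ens$frames[[frames[k]]]
    delta <- function(f) {
      f(fr, sets$complex) - f(fr, sets$receptor) - f(fr, sets$ligand)
    }
    dE_ele <- delta(function(fr, s) coulomb_energy(fr, top, s))
    dE_vdw <- delta(function(fr, s) lj_energy(fr, top, s))
    dG_pol <- delta(polar_fun)
    dG_np <- delta(function(fr, s)
      nonpolar_energy(shrake_rupley_sasa(fr, top, s, params)$total, params))
    series[k, ] <- c(dE_ele, dE_vdw, dE_ele + dE_vdw, dG_np,
                     dG_pol + dG_np,
                     dE_ele + dG_pol,
                     dE_ele + dE_vdw + dG_pol + dG_np)
  }
  summ <- data.frame(
    term = BREAKDOWN_TERMS,
    mean = colMeans(series),
    sample_std = apply(series, 2L, function(x)
      if (length(x) > 1L) stats::sd(x) else 0),
    n_frames = nf,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(solvent_model = solvent_model,
                 series = as.data.frame(series),
                 summary = summ,
                 ligand_partition = ligand_partition,
                 include_second_ligand = include_second_ligand,
                 protocol = "single-trajectory; -T dS_config = 0"),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("MM-", x$solvent_model, "/SA binding free energy (", x$protocol,
      ")\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %9.2f +/- %5.2f\n", s$term[i], s$mean[i],
                s$sample_std[i]))
  invisible(x)
}

#' Per-residue decomposition of the GB binding free energy
#'
#' Pairwise decomposition on the generalized Born path: ordered-pair gas
#' and GB energies are accumulated per atom (which splits every unordered
#' pair half-and-half between its partners), the change
#' complex-minus-species is attributed to the atom, and atoms are pooled
#' into receptor residues plus one ligand self-bucket (`residue` = "LIG").
#' Nonpolar contributions use per-atom SASA differences times gamma. The
#' contributions sum to the total `dG_bind` exactly per frame (to numerical
#' round-off), which the tests assert at 1e-6 kcal/mol.
#'
#' @inheritParams single_trajectory_mmgbsa
#' @param solvent_model only "GB" is supported; "PB" errors (the grid
#'   reaction field is not pairwise-decomposable here).
#' @return data.frame with `residue`, `resname`, `mean`, `sample_std`,
#'   `n_frames`; attribute `frame_matrix` holds the per-frame contributions
#'   (frames x residues).
#' @export
per_residue_decomposition <- function(ens, params = solvent_params(),
                                      ligand_partition = "ligand1",
                                      include_second_ligand = TRUE,
                                      solvent_model = "GB",
                                      frames = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  if (!identical(solvent_model, "GB"))
    stop("per_residue_decomposition: only the GB path is ",
         "pairwise-decomposable; PB is unsupported")
  top <- ens$topology
  sets <- mm_partitions(top, ligand_partition, include_second_ligand)
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  at <- top$atoms
  # bucket per atom of the complex: receptor resnum or the ligand bucket
  bucket <- ifelse(sets$complex %in% sets$ligand, "LIG",
                   as.character(at$resnum[sets$complex]))
  buckets <- unique(bucket)
  nf <- length(frames)
  contrib <- matrix(0, nf, length(buckets),
                    dimnames = list(NULL, buckets))
  pos_in <- function(sub) match(sub, sets$complex)
  q <- at$charge
  for (k in seq_len(nf)) {
    fr <- ens$frames[[frames[k]]]
    atom_d <- numeric(length(sets$complex))
    # gas-phase cross terms (ligand x receptor only; within-molecule terms
    # cancel in the single-trajectory difference)
    L <- fr[sets$ligand, , drop = FALSE]
    R <- fr[sets$receptor, , drop = FALSE]
    d2 <- outer(rowSums(L^2), rowSums(R^2), "+") - 2 * tcrossprod(L, R)
    r <- sqrt(pmax(d2, 0))
    if (min(r) < 1e-6) stop("per_residue_decomposition: overlapping atoms")
    e_ele <- COULOMB_KE * outer(q[sets$ligand], q[sets$receptor]) / r
    rmin <- outer(at$rmin_half[sets$ligand], at$rmin_half[sets$receptor],
                  "+")
    epsm <- sqrt(outer(at$epsilon[sets$ligand], at$epsilon[sets$receptor]))
    x6 <- (rmin / r)^6
    e_vdw <- epsm * (x6^2 - 2 * x6)
    cross <- e_ele + e_vdw
    li <- pos_in(sets$ligand); ri <- pos_in(sets$receptor)
    atom_d[li] <- atom_d[li] + rowSums(cross) / 2
    atom_d[ri] <- atom_d[ri] + colSums(cross) / 2
    # GB polar term: per-atom row sums, complex minus separated species
    Ec <- gb_energy_matrix(fr, top, sets$complex, params)
    Er <- gb_energy_matrix(fr, top, sets$receptor, params)
    El <- gb_energy_matrix(fr, top, sets$ligand, params)
    atom_d <- atom_d + rowSums(Ec)
    atom_d[ri] <- atom_d[ri] - rowSums(Er)
    atom_d[li] <- atom_d[li] - rowSums(El)
    # nonpolar term: per-atom SASA differences
    sc <- shrake_rupley_sasa(fr, top, sets$complex, params)$per_atom
    sr <- shrake_rupley_sasa(fr, top, sets$receptor, params)$per_atom
    sl <- shrake_rupley_sasa(fr, top, sets$ligand, params)$per_atom
    dsasa <- sc
    dsasa[ri] <- dsasa[ri] - sr
    dsasa[li] <- dsasa[li] - sl
    atom_d <- atom_d + params$gamma * dsasa
    contrib[k, ] <- vapply(buckets, function(b)
      sum(atom_d[bucket == b]), numeric(1))
  }
  resname <- vapply(buckets, function(b) {
    if (b == "LIG") return(ligand_partition)
    at$resname[at$resnum == as.integer(b) &
                 seq_len(nrow(at)) %in% sets$receptor][1L]
  }, character(1))
  out <- data.frame(
    residue = buckets,
    resname = unname(resname),
    mean = colMeans(contrib),
    sample_std = apply(contrib, 2L, function(x)
      if (length(x) > 1L) stats::sd(x) else 0),
    n_frames = nf,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "frame_matrix") <- contrib
  class(out) <- c("residue_contributions", "data.frame")
  out
}

#' Compare two binding free energy breakdowns by permutation test
#'
#' `ddG = mean(b) - mean(a)` on the per-frame `dG_bind` series, with a
#' two-sided permutation p-value: pooled frame labels are reshuffled
#' `n_resamples` times under a fixed seed and the absolute mean difference
#' compared against the observed one, `p = (1 + #{|T*| >= |T|}) /
#' (n_resamples + 1)`. This replaces contingency-table tests, which are not
#' defined for continuous per-frame energies.
#'
#' @param a,b `energy_breakdown` objects (or numeric per-frame dG_bind
#'   series).
#' @param n_resamples number of permutations (default 999).
#' @param seed RNG seed (required for reproducibility).
#' @return list with `ddG`, `p_value`, `n_resamples`, `n_a`, `n_b`.
#' @export
compare_breakdowns <- function(a, b, n_resamples = 999L, seed) {
  xa <- if (inherits(a, "energy_breakdown")) a$series$dG_bind else
    as.numeric(a)
  xb <- if (inherits(b, "energy_breakdown")) b$series$dG_bind else
    as.numeric(b)
  if (length(xa) < 2L || length(xb) < 2L)
    stop("compare_breakdowns: need at least 2 frames per series")
  if (missing(seed)) stop("compare_breakdowns: seed is required")
  obs <- mean(xb) - mean(xa)
  pooled <- c(xa, xb)
  na <- length(xa); n <- length(pooled)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  exceed <- 0L
  for (r in seq_len(n_resamples)) {
    ix <- sample.int(n, na)
    stat <- mean(pooled[-ix]) - mean(pooled[ix])
    if (abs(stat) >= abs(obs) - 1e-12) exceed <- exceed + 1L
  }
  list(ddG = obs,
       p_value = (1 + exceed) / (n_resamples + 1),
       n_resamples = n_resamples, n_a = na, n_b = length(xb))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
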