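#' @title Gas-phase nonbonded energetics
#' @name energy_nonbonded
#' @description
#' Pairwise Coulomb and 12-6 Lennard-Jones sums over a subset of atoms,
#' honouring 1-2/1-3 exclusions and Amber-style 1-4 scale factors from the
#' topology. No distance cutoff is applied: the systems handled here are
#' toy scale, and end-state scoring should not inherit the MD engine's
#' truncation. Energies in kcal/mol.
NULL

# all non-excluded pairs within `subset`, with per-pair scale factors
subset_pairs <- function(top, subset) {
  subset <- sort(as.integer(subset))
  m <- length(subset)
  if (m < 2L)
    return(list(i = integer(0), j = integer(0),
                ee = numeric(0), vdw = numeric(0)))
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  i <- subset[idx[, 1L]]; j <- subset[idx[, 2L]]
  n <- n_atoms(top)
  key <- function(a, b) (pmin(a, b) - 1) * n + pmax(a, b)
  pk <- key(i, j)
  excl <- if (nrow(top$exclusions))
    key(top$exclusions[, 1L], top$exclusions[, 2L]) else numeric(0)
  s14 <- if (nrow(top$scaled14))
    key(top$scaled14[, 1L], top$scaled14[, 2L]) else numeric(0)
  keep <- !(pk %in% excl)
  i <- i[keep]; j <- j[keep]; pk <- pk[keep]
  is14 <- pk %in% s14
  list(i = i, j = j,
       ee = ifelse(is14, top$ee_scale, 1),
       vdw = ifelse(is14, top$vdw_scale, 1))
}

pair_distances <- function(frame, i, j, min_sep = 1e-6) {
  d <- sqrt(rowSums((frame[i, , drop = FALSE] -
                     frame[j, , drop = FALSE])^2))
  if (length(d) && min(d) < min_sep)
    stop("overlapping atoms: pair (", i[which.min(d)], ", ",
         j[which.min(d)], ") at r = ", format(min(d)), " Angstrom")
  d
}

#' Coulomb energy of an atom subset
#'
#' Sum of `k_e q_i q_j / r_ij` over non-excluded pairs within the subset,
#' with 1-4 pairs scaled by the topology's `ee_scale`;
#' `k_e = 332.0637 kcal A / (mol e^2)`.
#'
#' @param frame `n x 3` coordinates (Angstrom).
#' @param top a `topology`.
#' @param subset atom indices (default: all).
#' @return energy, kcal/mol.
#' @export
coulomb_energy <- function(frame, top, subset = seq_len(n_atoms(top))) {
  p <- subset_pairs(top, subset)
  if (!length(p$i)) return(0)
  q <- top$atoms$charge
  r <- pair_distances(frame, p$i, p$j)
  sum(COULOMB_KE * q[p$i] * q[p$j] * p$ee / r)
}

#' Lennard-Jones energy of an atom subset
#'
#' 12-6 form with Lorentz-Berthelot-style combination
#' (`rmin_ij = rmin_half_i + rmin_half_j`, `eps_ij = sqrt(eps_i eps_j)`):
#' `E = sum eps_ij [(rmin_ij/r)^12 - 2 (rmin_ij/r)^6]`, so a pair at
#' `r = rmin_ij` contributes exactly `-eps_ij`. 1-4 pairs scaled by
#' `vdw_scale`.
#'
#' @inheritParams coulomb_energy
#' @return energy, kcal/mol.
#' @export
lj_energy <- function(frame, top, subset = seq_len(n_atoms(top))) {
  p <- subset_pairs(top, subset)
  if (!length(p$i)) return(0)
  at <- top$atoms
  r <- pair_distances(frame, p$i, p$j)
  rmin <- at$rmin_half[p$i] + at$rmin_half[p$j]
  eps <- sqrt(at$epsilon[p$i] * at$epsilon[p$j])
  x6 <- (rmin / r)^6
  sum(eps * (x6^2 - 2 * x6) * p$vdw)
}
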