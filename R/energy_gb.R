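#' Effective Born radii by pairwise descreening
#'
#' Hawkins-Cramer-Truhlar style Coulomb-field approximation: the inverse
#' effective radius of atom i is its inverse intrinsic radius (minus the
#' `gb_offset`) reduced by an analytic descreening integral over every
#' neighbour sphere. An isolated atom therefore recovers
#' `born_radius - gb_offset` exactly. Non-positive inverse radii are clamped
#' to an effective radius of 0.1 Angstrom with a warning.
#'
#' @param frame `n x 3` coordinates (Angstrom).
#' @param top a `topology` (uses `born_radius`).
#' @param subset atom indices; descreening only considers atoms within the
#'   subset (the species being solvated).
#' @param params a [solvent_params()] object (uses `gb_offset`).
#' @return numeric vector of effective radii (Angstrom), aligned with
#'   `subset`.
#' @export
effective_born_radii <- function(frame, top,
                                 subset = seq_len(n_atoms(top)),
                                 params = solvent_params()) {
  subset <- as.integer(subset)
  rho <- top$atoms$born_radius[subset] - params$gb_offset
  if (any(rho <= 0))
    stop("effective_born_radii: intrinsic radius <= gb_offset")
  m <- length(subset)
  inv <- 1 / rho
  if (m > 1L) {
    xyz <- frame[subset, , drop = FALSE]
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
    d2[d2 < 0] <- 0
    r <- sqrt(d2)
    for (i in seq_len(m)) {
      rij <- r[i, -i]; sj <- rho[-i]; ri <- rho[i]
      inv[i] <- inv[i] - sum(hct_descreen(ri, rij, sj))
    }
  }
  eff <- 1 / inv
  bad <- !is.finite(eff) | eff <= 0
  if (any(bad)) {
    warning("effective_born_radii: ", sum(bad),
            " non-positive effective radius value(s) clamped to 0.1 A")
    eff[bad] <- 0.1
  }
  eff
}

# analytic descreening integral of sphere (radius sj, centre distance r)
# seen from an atom of reduced intrinsic radius ri; equals
# (1/4pi) * integral over the sphere (excluding r' < ri) of dV / r'^4
hct_descreen <- function(ri, r, sj) {
  out <- numeric(length(r))
  U <- r + sj
  engulfs_i <- sj - r >= ri        # atom i fully inside sphere j
  buried_j <- U <= ri              # sphere j fully inside atom i: no term
  L <- pmax(ri, abs(r - sj))
  L[engulfs_i] <- (sj - r)[engulfs_i]
  act <- !buried_j
  if (any(act)) {
    La <- L[act]; Ua <- U[act]; ra <- r[act]; sa <- sj[act]
    term <- 0.5 * (1 / La - 1 / Ua +
                   (ra / 4) * (1 / Ua^2 - 1 / La^2) +
                   (1 / (2 * ra)) * log(La / Ua) +
                   (sa^2 / (4 * ra)) * (1 / La^2 - 1 / Ua^2))
    out[act] <- term
  }
  # engulfed case: the excluded core starts at ri, not L
  eng <- engulfs_i & !buried_j
  out[eng] <- out[eng] + (1 / ri - 1 / L[eng])
  out
}

gb_tau <- function(params)
  (1 / params$interior_dielectric - 1 / params$exterior_dielectric)

# Still's interpolation f_GB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))
gb_fgb <- function(r2, Ri, Rj) {
  RR <- outer(Ri, Rj)
  sqrt(r2 + RR * exp(-r2 / (4 * RR)))
}

# ordered-pair energy matrix E[i,j] = -0.5 ke tau qi qj / f_ij (self on the
# diagonal); total GB energy = sum(E); atom contribution = rowSums(E)
gb_energy_matrix <- function(frame, top, subset, params,
                             radii = NULL) {
  subset <- as.integer(subset)
  if (is.null(radii))
    radii <- effective_born_radii(frame, top, subset, params)
  q <- top$atoms$charge[subset]
  xyz <- frame[subset, , drop = FALSE]
  r2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  r2[r2 < 0] <- 0
  f <- gb_fgb(r2, radii, radii)
  -0.5 * COULOMB_KE * gb_tau(params) * outer(q, q) / f
}

#' Generalized Born polar solvation energy
#'
#' Still's pairwise formula over all ordered atom pairs of the subset,
#' including self terms:
#' `G = -(ke/2) (1/eps_in - 1/eps_out) sum_ij qi qj / f_GB(r, Ri, Rj)` with
#' `f_GB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))`. A single ion of charge
#' q and effective radius R recovers the analytic Born energy
#' `-(ke/2) (1/eps_in - 1/eps_out) q^2 / R`.
#'
#' @inheritParams effective_born_radii
#' @param radii optional precomputed effective radii for `subset`.
#' @return polar solvation energy, kcal/mol.
#' @export
gb_polar_energy <- function(frame, top, subset = seq_len(n_atoms(top)),
                            params = solvent_params(), radii = NULL) {
  sum(gb_energy_matrix(frame, top, subset, params, radii))
}
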