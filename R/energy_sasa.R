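#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sample-sphere algorithm: each atom's sphere is inflated by the
#' probe radius, covered with a deterministic golden-spiral point set, and a
#' point is accessible when it lies outside every other inflated sphere.
#' The per-atom area is the accessible point fraction times the inflated
#' sphere area. Sample points are owned by the generating atom; a point
#' exactly on another sphere's surface (within 1e-9) is ceded to the
#' lower-index atom, which keeps the union area invariant for exactly
#' coincident atoms.
#'
#' @param frame `n x 3` coordinates (Angstrom).
#' @param top a `topology` (`born_radius` is used as the atomic radius).
#' @param subset atom indices to include (occlusion only considers subset
#'   members).
#' @param params a [solvent_params()] (uses `probe_radius`,
#'   `sasa_n_points`).
#' @return list with `per_atom` (Angstrom^2, aligned with `subset`) and
#'   `total`.
#' @export
shrake_rupley_sasa <- function(frame, top, subset = seq_len(n_atoms(top)),
                               params = solvent_params()) {
  subset <- as.integer(subset)
  radii <- top$atoms$born_radius[subset] + params$probe_radius
  xyz <- frame[subset, , drop = FALSE]
  m <- length(subset)
  pts <- golden_spiral_points(params$sasa_n_points)
  per_atom <- numeric(m)
  if (m > 1L) {
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
    d2[d2 < 0] <- 0
  }
  for (i in seq_len(m)) {
    sphere <- sweep(pts * radii[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(pts))
    if (m > 1L) {
      nb <- which(d2[i, ] < (radii[i] + radii)^2)
      nb <- nb[nb != i]
      for (j in nb) {
        dj2 <- rowSums(sweep(sphere, 2L, xyz[j, ])^2)
        inside <- dj2 < radii[j]^2 - 1e-9 |
          (abs(dj2 - radii[j]^2) <= 1e-9 & j < i)
        acc <- acc & !inside
        if (!any(acc)) break
      }
    }
    per_atom[i] <- 4 * pi * radii[i]^2 * mean(acc)
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

# deterministic quasi-uniform unit-sphere covering (golden-angle spiral)
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Nonpolar solvation energy from SASA
#'
#' `G_nonpolar = gamma * SASA + beta`.
#'
#' @param sasa_total total solvent-accessible surface area, Angstrom^2.
#' @param params a [solvent_params()].
#' @return energy, kcal/mol.
#' @export
nonpolar_energy <- function(sasa_total, params = solvent_params()) {
  params$gamma * sasa_total + params$beta
}
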