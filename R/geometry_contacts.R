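#' Close-contact frame fractions per receptor residue
#'
#' For each receptor residue, the fraction of ensemble frames in which its
#' minimum heavy-atom distance to any heavy atom of the ligand partition is
#' strictly below `cutoff`. Hydrogens are excluded on both sides. All
#' receptor residues are reported explicitly, including those with
#' fraction 0. Fractions are monotone nondecreasing in `cutoff` by
#' construction (set inclusion).
#'
#' @param ens an `ensemble`.
#' @param ligand_partition partition label of the ligand of interest.
#' @param cutoff Angstrom, strict `<`; default 5.
#' @return a `contact_profile`: data.frame with `resnum`, `resname`,
#'   `contact_fraction`, plus attributes `cutoff` and `ligand_partition`.
#' @export
close_contact_fraction <- function(ens, ligand_partition = "ligand1",
                                   cutoff = 5.0) {
  stopifnot(inherits(ens, "ensemble"))
  top <- ens$topology
  lig <- partition_indices(top, ligand_partition)
  if (!length(lig)) stop("close_contact_fraction: partition '",
                         ligand_partition, "' is empty")
  heavy <- toupper(trimws(top$atoms$element)) != "H"
  lig <- lig[heavy[lig]]
  rec <- which(top$atoms$partition == "receptor" & heavy)
  if (!length(rec)) stop("close_contact_fraction: no receptor heavy atoms")
  res_atoms <- split(rec, top$atoms$resnum[rec])
  counts <- setNames(numeric(length(res_atoms)), names(res_atoms))
  lig_xyz <- lapply(ens$frames, function(fr) fr[lig, , drop = FALSE])
  for (k in seq_len(n_frames(ens))) {
    fr <- ens$frames[[k]]
    L <- lig_xyz[[k]]
    for (r in names(res_atoms)) {
      R <- fr[res_atoms[[r]], , drop = FALSE]
      d2 <- outer(rowSums(R^2), rowSums(L^2), "+") - 2 * tcrossprod(R, L)
      if (min(d2) < cutoff^2) counts[r] <- counts[r] + 1
    }
  }
  resname <- vapply(res_atoms, function(ix) top$atoms$resname[ix[1L]],
                    character(1))
  out <- data.frame(resnum = as.integer(names(res_atoms)),
                    resname = unname(resname),
                    contact_fraction = unname(counts) / n_frames(ens),
                    stringsAsFactors = FALSE)
  out <- out[order(out$resnum), ]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "ligand_partition") <- ligand_partition
  attr(out, "n_frames") <- n_frames(ens)
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Hydrogen-bond occupancy analysis
#'
#' Screens donor-acceptor pairs over the ensemble. A frame satisfies the
#' bond when the heavy-atom (donor-acceptor) distance is strictly below
#' `d_cut` and, in angle mode, the donor angle D-H...A at the hydrogen
#' exceeds `angle_cut` for at least one hydrogen bonded to the donor.
#' Occupancy is the satisfied-frame fraction; the mean distance is taken
#' over satisfying frames only.
#'
#' @param ens an `ensemble`.
#' @param donors,acceptors integer atom indices of donor and acceptor heavy
#'   atoms.
#' @param d_cut heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param angle_cut donor angle cutoff, degrees (default 120); set
#'   `check_angle = FALSE` for distance-only screening.
#' @param check_angle logical; require the D-H...A angle criterion.
#' @return data.frame with `donor_atom`, `acceptor_atom`,
#'   `heavy_atom_distance` (mean over satisfying frames, NA if never
#'   satisfied), `donor_angle` (mean, NA likewise), `occupancy`.
#' @export
hydrogen_bonds <- function(ens, donors, acceptors, d_cut = 3.5,
                           angle_cut = 120, check_angle = TRUE) {
  stopifnot(inherits(ens, "ensemble"))
  top <- ens$topology
  donors <- as.integer(donors); acceptors <- as.integer(acceptors)
  is_h <- toupper(trimws(top$atoms$element)) == "H"
  bonded_h <- lapply(donors, function(d) {
    nb <- c(top$bonds[top$bonds[, 1L] == d, 2L],
            top$bonds[top$bonds[, 2L] == d, 1L])
    nb[is_h[nb]]
  })
  if (check_angle && any(lengths(bonded_h) == 0L))
    stop("hydrogen_bonds: donor atom ",
         donors[which(lengths(bonded_h) == 0L)[1L]],
         " has no bonded hydrogen (required in angle mode)")
  out <- list()
  for (di in seq_along(donors)) {
    d <- donors[di]
    for (a in acceptors) {
      if (a == d) next
      sat <- logical(n_frames(ens))
      dist_f <- numeric(n_frames(ens))
      ang_f <- rep(NA_real_, n_frames(ens))
      for (k in seq_len(n_frames(ens))) {
        fr <- ens$frames[[k]]
        dist_f[k] <- sqrt(sum((fr[d, ] - fr[a, ])^2))
        ok <- dist_f[k] < d_cut
        if (ok && check_angle) {
          angs <- vapply(bonded_h[[di]], function(h) {
            v1 <- fr[d, ] - fr[h, ]; v2 <- fr[a, ] - fr[h, ]
            cosang <- sum(v1 * v2) /
              sqrt(sum(v1^2) * sum(v2^2))
            acos(max(-1, min(1, cosang))) * 180 / pi
          }, numeric(1))
          ang_f[k] <- max(angs)
          ok <- any(angs > angle_cut)
        }
        sat[k] <- ok
      }
      out[[length(out) + 1L]] <- data.frame(
        donor_atom = d, acceptor_atom = a,
        heavy_atom_distance = if (any(sat)) mean(dist_f[sat]) else NA_real_,
        donor_angle = if (any(sat) && check_angle)
          mean(ang_f[sat]) else NA_real_,
        occupancy = mean(sat))
    }
  }
  if (!length(out))
    return(data.frame(donor_atom = integer(0), acceptor_atom = integer(0),
                      heavy_atom_distance = numeric(0),
                      donor_angle = numeric(0), occupancy = numeric(0)))
  do.call(rbind, out)
}

#' Distance time series between two atoms
#'
#' @param ens an `ensemble`.
#' @param atom_a,atom_b distinct atom indices.
#' @return list with `distances` (per frame, Angstrom) and `summary`
#'   (a `series_summary`).
#' @export
distance_series <- function(ens, atom_a, atom_b) {
  stopifnot(inherits(ens, "ensemble"))
  if (atom_a == atom_b) stop("distance_series: identical atoms")
  n <- n_atoms(ens$topology)
  if (atom_a < 1L || atom_a > n || atom_b < 1L || atom_b > n)
    stop("distance_series: atom index outside 1..", n)
  d <- vapply(ens$frames, function(fr)
    sqrt(sum((fr[atom_a, ] - fr[atom_b, ])^2)), numeric(1))
  list(distances = d, summary = series_summary(d))
}
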