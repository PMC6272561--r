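#' Kabsch superposition
#'
#' Least-squares rigid superposition of `mobile` onto `reference` over the
#' selected atoms, via SVD of the covariance matrix with the usual
#' determinant correction so the rotation is proper (det = +1). The returned
#' RMSD is the global minimum over all rigid transforms.
#'
#' @param mobile,reference `n x 3` coordinate matrices (Angstrom).
#' @param selection atom indices used for the fit (default: all rows).
#' @return list with `rotation` (3x3), `translation` (length 3; the
#'   transform is `x %*% rotation + translation`), and `rmsd` (Angstrom,
#'   over the selection).
#' @export
kabsch_superpose <- function(mobile, reference,
                             selection = seq_len(nrow(reference))) {
  selection <- as.integer(selection)
  if (length(selection) < 1L) stop("kabsch_superpose: empty selection")
  if (max(selection) > nrow(mobile) || max(selection) > nrow(reference))
    stop("kabsch_superpose: selection outside coordinate range")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("kabsch_superpose: selection length mismatch")
  if (nrow(A) < 3L)
    stop("kabsch_superpose: need at least 3 selected atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  # collinearity check: rank of the centered reference must be >= 2
  if (sum(svd(B0)$d > 1e-8 * max(1, max(abs(B0)))) < 2L)
    stop("kabsch_superpose: selected atoms are collinear (underdetermined)")
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)         # A0 %*% R ~ B0
  A_fit <- A0 %*% R
  rmsd <- sqrt(mean(rowSums((A_fit - B0)^2)))
  list(rotation = R,
       translation = as.numeric(cb - ca %*% R),
       rmsd = rmsd)
}

apply_rigid <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2L, -fit$translation)
}

#' Per-frame backbone RMSD series
#'
#' Superposes every frame onto the reference over the selection and returns
#' the per-frame minimum RMSD, plus a `series_summary`.
#'
#' @param ens an `ensemble`.
#' @param reference reference coordinates (`n x 3` matrix or a frame index
#'   into `ens`, default frame 1).
#' @param selection atom indices (e.g. backbone N, CA, C).
#' @return list with `rmsd` (numeric per frame) and `summary`.
#' @export
backbone_rmsd_series <- function(ens, reference = 1L,
                                 selection = backbone_selection(ens$topology)) {
  stopifnot(inherits(ens, "ensemble"))
  ref <- if (is.matrix(reference)) reference else ens$frames[[reference]]
  vals <- vapply(ens$frames, function(fr)
    kabsch_superpose(fr, ref, selection)$rmsd, numeric(1))
  list(rmsd = vals, summary = series_summary(vals))
}

#' Backbone atom selection (N, CA, C)
#'
#' @param top a `topology`.
#' @return integer atom indices.
#' @export
backbone_selection <- function(top) {
  which(trimws(top$atoms$name) %in% c("N", "CA", "C"))
}

#' Per-residue RMS fluctuations
#'
#' Frames are first superposed onto the first frame over the selection; the
#' RMSF of an atom is the root-mean-square displacement about its time-mean
#' position (population normalisation, i.e. divide by the frame count), and
#' residue values average the atomic RMSF over the selected atoms of the
#' residue.
#'
#' @param ens an `ensemble` with at least 2 frames.
#' @param selection atom indices to analyse.
#' @param fit_selection atom indices for the superposition onto frame 1
#'   (defaults to `selection`); use a stable subset so mobile atoms do not
#'   drag the fit.
#' @return data.frame with `resnum`, `resname`, `rmsf` (Angstrom), plus an
#'   attribute `atom_rmsf` with per-atom values.
#' @export
rmsf_per_residue <- function(ens,
                             selection = seq_len(n_atoms(ens$topology)),
                             fit_selection = selection) {
  stopifnot(inherits(ens, "ensemble"))
  if (n_frames(ens) < 2L)
    stop("rmsf_per_residue: needs at least 2 frames")
  selection <- as.integer(selection)
  ref <- ens$frames[[1L]]
  aligned <- lapply(ens$frames, function(fr) {
    fit <- kabsch_superpose(fr, ref, fit_selection)
    apply_rigid(fr, fit)[selection, , drop = FALSE]
  })
  arr <- simplify2array(aligned)            # n_sel x 3 x n_frames
  mean_pos <- apply(arr, c(1L, 2L), mean)
  dev2 <- sweep(arr, c(1L, 2L), mean_pos)^2
  atom_rmsf <- sqrt(apply(dev2, 1L, mean) * 3)  # mean over 3*F entries -> *3
  at <- ens$topology$atoms[selection, ]
  res <- unique(at[, c("resnum", "resname")])
  res$rmsf <- vapply(seq_len(nrow(res)), function(i)
    mean(atom_rmsf[at$resnum == res$resnum[i]]), numeric(1))
  rownames(res) <- NULL
  attr(res, "atom_rmsf") <- atom_rmsf
  attr(res, "reference") <- "frame 1"
  res
}
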