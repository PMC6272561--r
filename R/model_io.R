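#' @title Topology and ensemble containers
#' @name model_io
#' @description
#' A `topology` carries the force-field side of the system: per-atom partial
#' charges (e), Lennard-Jones parameters (rmin/2 in Angstrom, epsilon in
#' kcal/mol), intrinsic Born radii (Angstrom), the bond graph, nonbonded
#' exclusions, and the partition of atoms into receptor / ligand1 / ligand2 /
#' cofactor molecules. An `ensemble` pairs a topology with an ordered list of
#' coordinate frames (Angstrom), the stand-in for molecular dynamics
#' snapshots. Units are Angstrom / kcal/mol / elementary charges throughout.
NULL

PARTITION_LABELS <- c("receptor", "ligand1", "ligand2", "cofactor")

#' Construct a topology
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resnum`, `resname`, `chain`, `charge`, `rmin_half`, `epsilon`,
#'   `born_radius`, `partition`.
#' @param bonds two-column matrix of 1-based atom indices (not serials).
#' @param rings optional list of integer vectors (atom indices) overriding
#'   ring perception.
#' @param exclusions optional two-column matrix of 1-2/1-3 excluded pairs;
#'   derived from `bonds` when `NULL`.
#' @param scaled14 optional two-column matrix of 1-4 pairs; derived from
#'   `bonds` when `NULL`.
#' @param ee_scale,vdw_scale 1-4 electrostatic and Lennard-Jones scale
#'   factors (Amber-style defaults 1/1.2 and 1/2).
#' @return an object of class `topology`.
#' @export
topology <- function(atoms, bonds = NULL, rings = NULL,
                     exclusions = NULL, scaled14 = NULL,
                     ee_scale = 1 / 1.2, vdw_scale = 0.5) {
  required <- c("serial", "name", "element", "resnum", "resname", "chain",
                "charge", "rmin_half", "epsilon", "born_radius", "partition")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("topology: atoms table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(atoms)
  if (n < 1L) stop("topology: no atoms")
  if (anyDuplicated(atoms$serial))
    stop("topology: duplicated atom serials")
  if (any(!atoms$partition %in% PARTITION_LABELS))
    stop("topology: unknown partition label(s): ",
         paste(unique(setdiff(atoms$partition, PARTITION_LABELS)),
               collapse = ", "))
  if (any(!is.finite(atoms$charge)))
    stop("topology: missing/non-finite charge")
  if (any(!is.finite(atoms$rmin_half)) || any(atoms$rmin_half <= 0))
    stop("topology: rmin_half must be present and > 0")
  if (any(!is.finite(atoms$epsilon)) || any(atoms$epsilon < 0))
    stop("topology: epsilon must be present and >= 0")
  if (any(!is.finite(atoms$born_radius)) || any(atoms$born_radius <= 0))
    stop("topology: born_radius must be present and > 0")

  bonds <- normalize_pairs(bonds, n, "bonds")
  if (is.null(exclusions) || is.null(scaled14)) {
    derived <- derive_exclusions(bonds, n)
    if (is.null(exclusions)) exclusions <- derived$exclusions
    if (is.null(scaled14)) scaled14 <- derived$scaled14
  } else {
    exclusions <- normalize_pairs(exclusions, n, "exclusions")
    scaled14 <- normalize_pairs(scaled14, n, "scaled14")
  }
  if (!is.null(rings)) {
    rings <- lapply(rings, as.integer)
    bad <- vapply(rings, function(r) any(r < 1L | r > n), logical(1))
    if (any(bad)) stop("topology: ring definition indexes outside atom range")
  }
  structure(list(
    atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
    bonds = bonds,
    exclusions = exclusions,
    scaled14 = scaled14,
    rings = rings,
    ee_scale = ee_scale,
    vdw_scale = vdw_scale
  ), class = "topology")
}

n_atoms <- function(top) nrow(top$atoms)

normalize_pairs <- function(pairs, n, what) {
  if (is.null(pairs) || NROW(pairs) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2L)
  if (any(pairs < 1L | pairs > n))
    stop("topology: ", what, " reference atom indices outside 1..", n)
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("topology: ", what, " contain a self pair")
  pairs <- cbind(i = pmin(pairs[, 1L], pairs[, 2L]),
                 j = pmax(pairs[, 1L], pairs[, 2L]))
  unique(pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE])
}

# 1-2 and 1-3 pairs (bond-graph distance 1 or 2) are excluded from nonbonded
# sums; distance-3 pairs are the scaled 1-4 set. BFS on the bond graph.
derive_exclusions <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1L]; j <- bonds[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  excl <- list(); s14 <- list()
  for (a in seq_len(n)) {
    d1 <- unique(adj[[a]])
    d2 <- setdiff(unique(unlist(adj[d1])), c(a, d1))
    d3 <- setdiff(unique(unlist(adj[d2])), c(a, d1, d2))
    near <- c(d1, d2)
    near <- near[near > a]
    d3 <- d3[d3 > a]
    if (length(near)) excl[[length(excl) + 1L]] <- cbind(a, near)
    if (length(d3)) s14[[length(s14) + 1L]] <- cbind(a, d3)
  }
  list(
    exclusions = normalize_pairs(do.call(rbind, excl), n, "exclusions"),
    scaled14 = normalize_pairs(do.call(rbind, s14), n, "scaled14")
  )
}

#' Atom indices of a partition
#'
#' @param top a `topology`.
#' @param labels one or more partition labels.
#' @return integer vector of atom indices.
#' @export
partition_indices <- function(top, labels) {
  unknown <- setdiff(labels, PARTITION_LABELS)
  if (length(unknown))
    stop("unknown partition label(s): ", paste(unknown, collapse = ", "))
  which(top$atoms$partition %in% labels)
}

#' Construct an ensemble from a topology and a list of coordinate frames
#'
#' @param top a `topology`.
#' @param frames list of `n_atoms x 3` numeric matrices (Angstrom).
#' @param model_indices optional integer model numbers (default 1..n).
#' @return an object of class `ensemble`.
#' @export
ensemble <- function(top, frames, model_indices = NULL) {
  stopifnot(inherits(top, "topology"))
  if (length(frames) < 1L) stop("ensemble: needs at least one frame")
  n <- n_atoms(top)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!is.matrix(fr) || ncol(fr) != 3L)
      stop("ensemble: frame ", k, " is not an n x 3 matrix")
    if (nrow(fr) != n)
      stop("ensemble: frame ", k, " has ", nrow(fr),
           " atoms, topology has ", n)
    if (any(!is.finite(fr)))
      stop("ensemble: frame ", k, " contains non-finite coordinates")
    dimnames(frames[[k]]) <- NULL
    storage.mode(frames[[k]]) <- "double"
  }
  if (is.null(model_indices)) model_indices <- seq_along(frames)
  structure(list(topology = top, frames = frames,
                 model_indices = as.integer(model_indices)),
            class = "ensemble")
}

n_frames <- function(ens) length(ens$frames)

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frames x %d atoms (%s)\n",
              n_frames(x), n_atoms(x$topology),
              paste(sprintf("%s:%d", PARTITION_LABELS,
                            vapply(PARTITION_LABELS, function(p)
                              sum(x$topology$atoms$partition == p),
                              integer(1))),
                    collapse = " ")))
  invisible(x)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d bonds, %d exclusions, %d 1-4 pairs\n",
              n_atoms(x), nrow(x$bonds), nrow(x$exclusions),
              nrow(x$scaled14)))
  invisible(x)
}

# ---- topology sidecar (JSON) -------------------------------------------

#' Read a topology sidecar file
#'
#' The sidecar is a JSON document with top-level keys `atoms` (records with
#' `serial,name,element,resnum,resname,chain,charge,rmin_half,epsilon,
#' born_radius,partition`), `bonds` (list of serial pairs), optional `rings`
#' (lists of serials) and optional `scaled_14_factors`
#' (`ee_scale`, `vdw_scale`). Exclusions and 1-4 pairs are derived from the
#' bond graph. Partitions must be disjoint (one label per atom) and cover
#' all atoms.
#'
#' @param path file path.
#' @return a `topology`.
#' @export
read_topology <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$atoms)) stop("read_topology: no 'atoms' key in ", path)
  atoms <- as.data.frame(doc$atoms, stringsAsFactors = FALSE)
  if (is.list(atoms$partition) ||
      any(vapply(atoms$partition, length, integer(1)) != 1L))
    stop("read_topology: an atom is assigned to more than one partition")
  atoms$partition <- unlist(atoms$partition)
  for (col in c("charge", "rmin_half", "epsilon", "born_radius")) {
    if (is.null(atoms[[col]]) || any(is.na(atoms[[col]])))
      stop("read_topology: missing ", col, " for at least one atom")
  }
  serial_to_idx <- setNames(seq_len(nrow(atoms)), atoms$serial)
  map_serials <- function(m, what) {
    if (is.null(m) || NROW(m) == 0L) return(NULL)
    m <- matrix(as.integer(as.matrix(m)), ncol = 2L)
    idx <- matrix(serial_to_idx[as.character(m)], ncol = 2L)
    if (any(is.na(idx)))
      stop("read_topology: ", what, " reference unknown serial(s)")
    idx
  }
  bonds <- map_serials(doc$bonds, "bonds")
  rings <- NULL
  if (!is.null(doc$rings)) {
    ring_list <- if (is.matrix(doc$rings))
      split(doc$rings, row(doc$rings)) else as.list(doc$rings)
    rings <- lapply(ring_list, function(r) {
      idx <- serial_to_idx[as.character(as.integer(unlist(r)))]
      if (any(is.na(idx)))
        stop("read_topology: rings reference unknown serial(s)")
      as.integer(idx)
    })
  }
  ee <- 1 / 1.2; vw <- 0.5
  if (!is.null(doc$scaled_14_factors)) {
    if (!is.null(doc$scaled_14_factors$ee_scale))
      ee <- doc$scaled_14_factors$ee_scale
    if (!is.null(doc$scaled_14_factors$vdw_scale))
      vw <- doc$scaled_14_factors$vdw_scale
  }
  topology(atoms, bonds = bonds, rings = rings,
           ee_scale = ee, vdw_scale = vw)
}

#' Write a topology sidecar file
#'
#' @param top a `topology`.
#' @param path output file path.
#' @export
write_topology <- function(top, path) {
  serials <- top$atoms$serial
  doc <- list(
    atoms = top$atoms,
    bonds = matrix(serials[top$bonds], ncol = 2L),
    scaled_14_factors = list(ee_scale = top$ee_scale,
                             vdw_scale = top$vdw_scale)
  )
  if (!is.null(top$rings))
    doc$rings <- lapply(top$rings, function(r) serials[r])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- multi-model PDB ----------------------------------------------------

#' Read a (multi-model) PDB file into an ensemble
#'
#' Parses ATOM/HETATM records per wwPDB v3.3 fixed columns. Each
#' MODEL/ENDMDL block becomes one frame; a file without MODEL records yields
#' a single-frame ensemble. Atom matching against the topology is by order,
#' with the serial field as a checked redundancy. Alternate locations and
#' insertion codes are rejected.
#'
#' @param path PDB file path.
#' @param top the `topology` describing the same system.
#' @return an `ensemble`.
#' @export
read_ensemble <- function(path, top) {
  stopifnot(inherits(top, "topology"))
  lines <- readLines(path)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_endmdl <- startsWith(lines, "ENDMDL")
  n <- n_atoms(top)

  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id[] <- 1L
  atom_lines <- which(is_atom)
  if (!length(atom_lines)) stop("read_ensemble: no ATOM/HETATM records in ",
                                path)
  if (any(is_model) && any(model_id[atom_lines] == 0L))
    stop("read_ensemble: ATOM record before first MODEL at line ",
         atom_lines[which(model_id[atom_lines] == 0L)[1L]])

  alt <- substr(lines[atom_lines], 17L, 17L)
  icode <- substr(lines[atom_lines], 27L, 27L)
  if (any(alt != " "))
    stop("read_ensemble: alternate location indicators not supported (line ",
         atom_lines[which(alt != " ")[1L]], ")")
  if (any(icode != " "))
    stop("read_ensemble: insertion codes not supported (line ",
         atom_lines[which(icode != " ")[1L]], ")")

  parse_num <- function(txt, from, to, what) {
    s <- substr(txt, from, to)
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad))
      stop("read_ensemble: unparsable ", what, " field at line ",
           atom_lines[bad[1L]], ": '", s[bad[1L]], "'")
    v
  }
  txt <- lines[atom_lines]
  serial <- as.integer(parse_num(txt, 7L, 11L, "serial"))
  x <- parse_num(txt, 31L, 38L, "x coordinate")
  y <- parse_num(txt, 39L, 46L, "y coordinate")
  z <- parse_num(txt, 47L, 54L, "z coordinate")

  split_idx <- split(seq_along(atom_lines), model_id[atom_lines])
  frames <- vector("list", length(split_idx))
  model_numbers <- integer(length(split_idx))
  expected_serials <- top$atoms$serial
  for (k in seq_along(split_idx)) {
    idx <- split_idx[[k]]
    if (length(idx) != n) {
      got <- serial[idx]
      miss <- setdiff(expected_serials, got)
      extra <- setdiff(got, expected_serials)
      detail <- if (length(miss))
        paste0("first missing serial ", miss[1L])
      else if (length(extra))
        paste0("first unexpected serial ", extra[1L])
      else paste0("serial ", got[length(got)], " duplicated or misplaced")
      stop("read_ensemble: model ", k, " has ", length(idx),
           " atoms, topology has ", n, " (", detail, ")")
    }
    mism <- which(serial[idx] != expected_serials)
    if (length(mism))
      stop("read_ensemble: model ", k, " atom order mismatch at serial ",
           serial[idx][mism[1L]], " (expected ",
           expected_serials[mism[1L]], ")")
    frames[[k]] <- cbind(x[idx], y[idx], z[idx])
    model_numbers[k] <- k
  }
  mdl_nums <- suppressWarnings(
    as.integer(sub("^MODEL\\s+", "", lines[is_model])))
  if (length(mdl_nums) == length(frames) && !anyNA(mdl_nums))
    model_numbers <- mdl_nums
  ensemble(top, frames, model_numbers)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Always emits MODEL/ENDMDL pairs (one per frame) and a final END record.
#' Coordinates are written with 3 decimals (the PDB fixed-width precision),
#' so a round trip reproduces them to 0.001 Angstrom.
#'
#' @param ens an `ensemble`.
#' @param path output file path.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  if (n_frames(ens) < 1L) stop("write_ensemble: empty frame list")
  at <- ens$topology$atoms
  rng <- range(unlist(lapply(ens$frames, range)))
  if (rng[1L] < -999.999 || rng[2L] > 9999.999)
    stop("write_ensemble: coordinates exceed PDB fixed-width field range")
  name4 <- ifelse(nchar(at$name) < 4L, paste0(" ", at$name), at$name)
  name4 <- formatC(name4, width = -4L)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", ens$model_indices[k]), con)
    fr <- ens$frames[[k]]
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$serial, name4, at$resname, at$chain, at$resnum,
      fr[, 1L], fr[, 2L], fr[, 3L], toupper(at$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
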