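#' Perceive aromatic-sized rings from the bond graph
#'
#' Enumerates simple cycles of 5-6 atoms in the topology bond graph (DFS
#' with canonical-start pruning, so each undirected cycle is found once),
#' then filters by planarity in the reference frame:
#' the RMS out-of-plane deviation from the least-squares plane of the
#' members must not exceed `planarity_tol`. Fused bicyclics therefore yield
#' their two constituent rings, not the outer envelope cycle (capped at
#' size 6). Explicit `rings` entries in the topology override perception
#' and are trusted as given (no planarity screening), so heavily jittered
#' frames cannot silently drop a known aromatic ring.
#'
#' @param top a `topology`.
#' @param reference reference frame coordinates (`n x 3`).
#' @param planarity_tol maximum RMS out-of-plane deviation, Angstrom.
#' @return list of `ring_system` objects: `ring_id`, `member_atoms`
#'   (ordered along the cycle), `owner_partition`.
#' @export
perceive_rings <- function(top, reference, planarity_tol = 0.15) {
  stopifnot(inherits(top, "topology"))
  explicit <- !is.null(top$rings)
  cycles <- if (explicit) {
    top$rings
  } else {
    enumerate_cycles(top$bonds, n_atoms(top), min_len = 5L, max_len = 6L)
  }
  # explicit ring lists may repeat; deduplicate on the member set
  keys <- vapply(cycles, function(m) paste(sort(m), collapse = "-"),
                 character(1))
  cycles <- cycles[!duplicated(keys)]
  out <- list()
  for (m in cycles) {
    coords <- reference[m, , drop = FALSE]
    pl <- plane_fit(coords)
    if (explicit || pl$rms <= planarity_tol) {
      part <- unique(top$atoms$partition[m])
      out[[length(out) + 1L]] <- structure(list(
        ring_id = length(out) + 1L,
        member_atoms = as.integer(m),
        owner_partition = if (length(part) == 1L) part else "mixed"
      ), class = "ring_system")
    }
  }
  out
}

# all simple cycles of bounded length, each reported once: the DFS roots a
# cycle at its smallest vertex and only walks to larger vertices, with the
# second vertex kept below the last to kill the mirror orientation
enumerate_cycles <- function(bonds, n, min_len = 5L, max_len = 6L) {
  if (NROW(bonds) == 0L) return(list())
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1L]; j <- bonds[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  path <- integer(max_len)
  on_path <- logical(n)
  walk <- function(v, depth, root) {
    path[depth] <<- v
    on_path[v] <<- TRUE
    for (w in adj[[v]]) {
      if (w == root && depth >= min_len && path[2L] < v) {
        out[[length(out) + 1L]] <<- path[seq_len(depth)]
      } else if (w > root && !on_path[w] && depth < max_len) {
        walk(w, depth + 1L, root)
      }
    }
    on_path[v] <<- FALSE
  }
  for (root in seq_len(n)) walk(root, 1L, root)
  out
}

# least-squares plane through points: centroid + normal (smallest right
# singular vector); rms = RMS distance of points to the plane
plane_fit <- function(coords) {
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2L, centroid)
  s <- svd(centered)
  if (s$d[2L] < 1e-8 * max(1, s$d[1L]))
    stop("plane_fit: points are collinear")
  normal <- s$v[, 3L]
  dist <- centered %*% normal
  list(centroid = centroid, normal = as.numeric(normal),
       rms = sqrt(mean(dist^2)))
}

#' Centroid distance and inter-plane angle of two rings
#'
#' Centroid = unweighted mean of member coordinates; plane normal =
#' least-squares fit over all members (robust to puckering); the angle is
#' `acos(|n_a . n_b|)` folded into [0, 90] degrees, so antiparallel normals
#' give 0. Symmetric under swapping the rings.
#'
#' @param frame `n x 3` coordinates.
#' @param ring_a,ring_b `ring_system` objects (or integer index vectors).
#' @return list with `centroid_distance` (Angstrom) and `interplane_angle`
#'   (degrees).
#' @export
ring_pair_geometry <- function(frame, ring_a, ring_b) {
  ma <- if (inherits(ring_a, "ring_system")) ring_a$member_atoms else ring_a
  mb <- if (inherits(ring_b, "ring_system")) ring_b$member_atoms else ring_b
  pa <- plane_fit(frame[ma, , drop = FALSE])
  pb <- plane_fit(frame[mb, , drop = FALSE])
  d <- sqrt(sum((pa$centroid - pb$centroid)^2))
  cosang <- abs(sum(pa$normal * pb$normal))
  ang <- acos(min(1, cosang)) * 180 / pi
  list(centroid_distance = d, interplane_angle = ang)
}

#' Classify a ring-pair inter-plane angle
#'
#' Parallel below `parallel_max`, perpendicular above `perpendicular_min`,
#' tilted in between. The thresholds are conventions, not physics, and are
#' exposed in the analysis config.
#'
#' @param interplane_angle degrees, in [0, 90].
#' @param parallel_max,perpendicular_min class boundaries, degrees.
#' @return one of "parallel", "tilted", "perpendicular".
#' @export
classify_stacking <- function(interplane_angle, parallel_max = 30,
                              perpendicular_min = 60) {
  if (any(interplane_angle < 0 | interplane_angle > 90))
    stop("classify_stacking: angle outside [0, 90]")
  ifelse(interplane_angle < parallel_max, "parallel",
         ifelse(interplane_angle > perpendicular_min, "perpendicular",
                "tilted"))
}

#' Detect pi-pi stacking over an ensemble
#'
#' For every frame and every ring pair spanning two distinct partitions
#' (by default; set `cross_partition_only = FALSE` to include all pairs),
#' a stacking record is emitted when the centroid distance is strictly
#' below `cutoff` (the 7 Angstrom aromatic-interaction criterion). Per-pair
#' summaries are given both over qualifying frames only and over all frames
#' (the two averaging conventions differ whenever occupancy < 1).
#'
#' @param ens an `ensemble`.
#' @param rings list of `ring_system` (default: perceived from frame 1).
#' @param cutoff centroid-distance cutoff, Angstrom (strict `<`).
#' @param cross_partition_only only pair rings from different partitions.
#' @param parallel_max,perpendicular_min class thresholds passed to
#'   [classify_stacking()].
#' @return list with `records` (data.frame: frame_index, ring_a, ring_b,
#'   centroid_distance, interplane_angle, stacking_class) and `summaries`
#'   (data.frame per pair: occupancy, qualifying-frame and all-frame
#'   mean/std of distance and angle).
#' @export
detect_stacking <- function(ens, rings = NULL, cutoff = 7.0,
                            cross_partition_only = TRUE,
                            parallel_max = 30, perpendicular_min = 60) {
  stopifnot(inherits(ens, "ensemble"))
  if (is.null(rings)) rings <- perceive_rings(ens$topology, ens$frames[[1L]])
  if (length(rings) < 2L)
    return(list(records = empty_stacking_records(),
                summaries = empty_stacking_summaries()))
  pairs <- utils::combn(length(rings), 2L)
  if (cross_partition_only) {
    keep <- apply(pairs, 2L, function(p)
      rings[[p[1L]]]$owner_partition != rings[[p[2L]]]$owner_partition)
    pairs <- pairs[, keep, drop = FALSE]
  }
  if (!ncol(pairs))
    return(list(records = empty_stacking_records(),
                summaries = empty_stacking_summaries()))
  rec <- list(); summ <- list()
  for (pc in seq_len(ncol(pairs))) {
    ia <- pairs[1L, pc]; ib <- pairs[2L, pc]
    geo <- vapply(ens$frames, function(fr) {
      g <- ring_pair_geometry(fr, rings[[ia]], rings[[ib]])
      c(g$centroid_distance, g$interplane_angle)
    }, numeric(2))
    dists <- geo[1L, ]; angs <- geo[2L, ]
    qual <- dists < cutoff
    if (any(qual)) {
      rec[[length(rec) + 1L]] <- data.frame(
        frame_index = which(qual),
        ring_a = rings[[ia]]$ring_id, ring_b = rings[[ib]]$ring_id,
        centroid_distance = dists[qual], interplane_angle = angs[qual],
        stacking_class = classify_stacking(angs[qual], parallel_max,
                                           perpendicular_min),
        stringsAsFactors = FALSE)
    }
    qd <- if (any(qual)) series_summary(dists[qual]) else NULL
    qa <- if (any(qual)) series_summary(angs[qual]) else NULL
    summ[[length(summ) + 1L]] <- data.frame(
      ring_a = rings[[ia]]$ring_id, ring_b = rings[[ib]]$ring_id,
      partition_a = rings[[ia]]$owner_partition,
      partition_b = rings[[ib]]$owner_partition,
      occupancy = mean(qual),
      n_qualifying = sum(qual),
      dist_mean = if (any(qual)) qd$mean else NA_real_,
      dist_std = if (any(qual)) qd$sample_std else NA_real_,
      angle_mean = if (any(qual)) qa$mean else NA_real_,
      angle_std = if (any(qual)) qa$sample_std else NA_real_,
      dist_mean_all = mean(dists), dist_std_all = stats::sd(dists),
      angle_mean_all = mean(angs), angle_std_all = stats::sd(angs),
      stringsAsFactors = FALSE)
  }
  list(records = if (length(rec)) do.call(rbind, rec)
       else empty_stacking_records(),
       summaries = do.call(rbind, summ))
}

empty_stacking_records <- function() {
  data.frame(frame_index = integer(0), ring_a = integer(0),
             ring_b = integer(0), centroid_distance = numeric(0),
             interplane_angle = numeric(0), stacking_class = character(0),
             stringsAsFactors = FALSE)
}

empty_stacking_summaries <- function() {
  data.frame(ring_a = integer(0), ring_b = integer(0),
             partition_a = character(0), partition_b = character(0),
             occupancy = numeric(0), n_qualifying = integer(0),
             dist_mean = numeric(0), dist_std = numeric(0),
             angle_mean = numeric(0), angle_std = numeric(0),
             dist_mean_all = numeric(0), dist_std_all = numeric(0),
             angle_mean_all = numeric(0), angle_std_all = numeric(0),
             stringsAsFactors = FALSE)
}
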