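## Trajectory container: coords is an [n_frames, n_atoms, 3] array in nm,
## atoms a data.frame(chain, resid, resname, atom), dt the frame spacing in
## ns, box an optional periodic box applied to every frame.

#' Construct an in-memory trajectory
#'
#' @param coords numeric array `[n_frames, n_atoms, 3]`, nm.
#' @param atoms data.frame with columns chain, resid, resname, atom.
#' @param dt frame spacing in ns (uniform).
#' @param box optional periodic box (see [pair_distance()]).
#' @return a `qw_trajectory`.
#' @export
trajectory <- function(coords, atoms, dt, box = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L,
            dim(coords)[2] == nrow(atoms), dt > 0)
  structure(list(coords = coords, atoms = atoms, dt = dt, box = box),
            class = "qw_trajectory")
}

#' Load a trajectory from a multi-model PDB (or PDB + DCD) file
#'
#' Multi-model PDB files are the plain-text trajectory interchange used
#' here; a DCD file may accompany a single-model PDB topology.
#'
#' @param topology PDB file naming the atoms.
#' @param trajectory_file optional DCD file; if missing, the topology's own
#'   MODEL records are the frames.
#' @param dt frame spacing in ns.
#' @param box optional periodic box.
#' @return a `qw_trajectory`.
#' @export
read_trajectory <- function(topology, trajectory_file = NULL, dt, box = NULL) {
  pdb <- bio3d::read.pdb(topology, verbose = FALSE, multi = TRUE)
  xyz <- if (is.null(trajectory_file)) pdb$xyz else bio3d::read.dcd(trajectory_file)
  nfr <- nrow(xyz); nat <- ncol(xyz) / 3L
  coords <- aperm(array(t(xyz), dim = c(3L, nat, nfr)), c(3L, 2L, 1L)) / 10
  atoms <- data.frame(chain = as.character(pdb$atom$chain),
                      resid = pdb$atom$resno,
                      resname = as.character(pdb$atom$resid),
                      atom = as.character(pdb$atom$elety),
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms, dt = dt, box = box)
}

#' Select atom indices in a trajectory
#'
#' @param traj a `qw_trajectory`.
#' @param chain,resid,resname,atom optional filters; each may be a vector.
#' @return integer indices into the trajectory's atom table.
#' @export
select_atoms <- function(traj, chain = NULL, resid = NULL, resname = NULL,
                         atom = NULL) {
  at <- traj$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(resname)) keep <- keep & at$resname %in% resname
  if (!is.null(atom)) keep <- keep & at$atom %in% atom
  idx <- which(keep)
  if (length(idx) == 0L) stop("selection matches no atoms", call. = FALSE)
  idx
}

## Water-oxygen indices of a trajectory.
water_indices <- function(traj) {
  which(traj$atoms$resname %in% water_resnames() &
          traj$atoms$atom %in% c("O", "OW", "OH2"))
}

#' Define a contact
#'
#' A contact is a donor/acceptor pair of atom selections with a bridge
#' order: 0 for a direct heavy-atom H-bond, k >= 1 for a bridge of k
#' sequential water molecules. The criterion is purely distance-based:
#' every link of the chain must be strictly below `cutoff` (default
#' 0.35 nm, the heavy-atom H-bond distance).
#'
#' @param donor,acceptor integer atom indices (into the trajectory atoms).
#' @param bridge_order integer in 0:3.
#' @param cutoff nm, > 0.
#' @param label optional contact name.
#' @return a `qw_contact_spec`.
#' @export
contact_spec <- function(donor, acceptor, bridge_order = 0L, cutoff = 0.35,
                         label = NULL) {
  stopifnot(cutoff > 0, bridge_order %in% 0:3,
            length(donor) >= 1L, length(acceptor) >= 1L)
  structure(list(donor = donor, acceptor = acceptor,
                 bridge_order = as.integer(bridge_order), cutoff = cutoff,
                 label = label %||% sprintf("contact_k%d", bridge_order)),
            class = "qw_contact_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

frame_coords <- function(traj, frame) {
  matrix(traj$coords[frame, , ], ncol = 3L)
}

## Min distance (nm) from each row of `set` to a group, minimum-image aware.
min_dist_to_group <- function(group, set, box) {
  d2 <- rep(Inf, nrow(set))
  for (i in seq_len(nrow(group)))
    d2 <- pmin(d2, dist2_point_set(group[i, ], set, box))
  sqrt(d2)
}

#' Direct H-bond detection in one frame
#'
#' Formed iff the minimum donor-acceptor heavy-atom distance is strictly
#' below the cutoff.
#'
#' @param traj a `qw_trajectory`.
#' @param frame frame index.
#' @param spec a `qw_contact_spec` with `bridge_order = 0`.
#' @return logical.
#' @export
detect_direct <- function(traj, frame, spec) {
  stopifnot(spec$bridge_order == 0L)
  xyz <- frame_coords(traj, frame)
  min_group_distance(xyz[spec$donor, , drop = FALSE],
                     xyz[spec$acceptor, , drop = FALSE],
                     traj$box) < spec$cutoff
}

#' Water-bridge detection in one frame
#'
#' A k-water bridge is formed when an ordered chain of k distinct water
#' oxygens connects donor to acceptor with every consecutive link (donor-w1,
#' w1-w2, ..., wk-acceptor) strictly below the cutoff. Water identity is
#' reported but is irrelevant to the per-frame state: the bridged state is
#' defined frame by frame, so a water exchanging with an immediate
#' replacement still counts as formed.
#'
#' @param traj a `qw_trajectory`.
#' @param frame frame index.
#' @param spec a `qw_contact_spec` with `bridge_order >= 1`.
#' @param waters water-oxygen atom indices; defaults to all waters in the
#'   trajectory.
#' @return list(formed = logical, waters = integer vector of one bridging
#'   chain, empty when not formed).
#' @export
detect_bridge <- function(traj, frame, spec, waters = water_indices(traj)) {
  k <- spec$bridge_order
  stopifnot(k >= 1L)
  if (length(waters) == 0L) stop("no water oxygens supplied", call. = FALSE)
  xyz <- frame_coords(traj, frame)
  w <- xyz[waters, , drop = FALSE]
  cut <- spec$cutoff
  dd <- min_dist_to_group(xyz[spec$donor, , drop = FALSE], w, traj$box)
  da <- min_dist_to_group(xyz[spec$acceptor, , drop = FALSE], w, traj$box)
  near_d <- which(dd < cut)
  near_a <- which(da < cut)
  if (length(near_d) == 0L || length(near_a) == 0L)
    return(list(formed = FALSE, waters = integer()))
  if (k == 1L) {
    hit <- intersect(near_d, near_a)
    return(list(formed = length(hit) > 0L,
                waters = waters[hit[seq_len(min(1L, length(hit)))]]))
  }
  ## water-water adjacency restricted to candidates reachable from either end
  cand <- sort(unique(c(near_d, near_a,
                        which(dd < k * cut | da < k * cut))))
  wmat <- w[cand, , drop = FALSE]
  n <- nrow(wmat)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    adj[i, ] <- dist2_point_set(wmat[i, ], wmat, traj$box) < cut^2
  diag(adj) <- FALSE
  d_ok <- match(near_d, cand)
  a_ok <- match(near_a, cand)
  ## DFS for a simple chain of exactly k waters from a donor-near to an
  ## acceptor-near oxygen
  chain <- find_chain(adj, d_ok, a_ok, k)
  if (is.null(chain)) list(formed = FALSE, waters = integer())
  else list(formed = TRUE, waters = waters[cand[chain]])
}

## Depth-first search for a simple path w1..wk with w1 in starts, wk in ends.
find_chain <- function(adj, starts, ends, k) {
  recurse <- function(path) {
    last <- path[length(path)]
    if (length(path) == k) {
      if (last %in% ends) return(path)
      return(NULL)
    }
    for (nxt in which(adj[last, ])) {
      if (nxt %in% path) next
      r <- recurse(c(path, nxt))
      if (!is.null(r)) return(r)
    }
    NULL
  }
  for (s in starts) {
    r <- recurse(s)
    if (!is.null(r)) return(r)
  }
  NULL
}

#' Per-frame contact series with occupancy, moving average and lifetimes
#'
#' @param traj a `qw_trajectory` (uniform frame spacing).
#' @param spec a `qw_contact_spec`.
#' @param waters water-oxygen indices (needed when `bridge_order >= 1`).
#' @param window moving-average window in ns (rectangular, centred,
#'   truncated at the edges). Default 1 ns.
#' @param gap_tolerance lifetime gap tolerance in ns; interruptions no longer
#'   than this do not terminate an event. Default one frame interval.
#' @return a `qw_contact_series`: list with `formed` (logical per frame),
#'   `occupancy`, `moving_avg`, `lifetimes` (ns), `dt`, `spec`.
#' @export
contact_series <- function(traj, spec, waters = NULL, window = 1,
                           gap_tolerance = NULL) {
  nfr <- dim(traj$coords)[1]
  if (nfr < 2L) stop("need at least 2 frames", call. = FALSE)
  if (spec$bridge_order >= 1L && is.null(waters)) waters <- water_indices(traj)
  formed <- vapply(seq_len(nfr), function(f) {
    if (spec$bridge_order == 0L) detect_direct(traj, f, spec)
    else detect_bridge(traj, f, spec, waters)$formed
  }, logical(1))
  contact_series_from_logical(formed, dt = traj$dt, spec = spec,
                              window = window, gap_tolerance = gap_tolerance)
}

#' Build a contact series from a logical formation record
#'
#' Entry point for precomputed or synthetic (telegraph) formation records.
#'
#' @param formed logical vector, one element per frame.
#' @param dt frame spacing in ns.
#' @param spec optional `qw_contact_spec` carried along.
#' @inheritParams contact_series
#' @return a `qw_contact_series`.
#' @export
contact_series_from_logical <- function(formed, dt, spec = NULL, window = 1,
                                        gap_tolerance = NULL) {
  stopifnot(is.logical(formed), length(formed) >= 1L, dt > 0)
  if (is.null(gap_tolerance)) gap_tolerance <- dt
  events <- contact_events(formed, dt, gap_tolerance)
  structure(list(formed = formed, dt = dt, spec = spec,
                 occupancy = mean(formed),
                 moving_avg = moving_average(as.numeric(formed),
                                             max(1L, round(window / dt))),
                 lifetimes = events$durations,
                 gap_tolerance = gap_tolerance),
            class = "qw_contact_series")
}

#' @export
print.qw_contact_series <- function(x, ...) {
  cat(sprintf("Contact series (%s): %d frames, occupancy %.3f, %d events, mean lifetime %.4g ns\n",
              if (is.null(x$spec)) "unnamed" else x$spec$label,
              length(x$formed), x$occupancy, length(x$lifetimes),
              if (length(x$lifetimes)) mean(x$lifetimes) else 0))
  invisible(x)
}

#' Centred rectangular moving average
#'
#' Window truncated at the series edges, so the mean of the averaged series
#' equals the mean of the raw series.
#'
#' @param x numeric vector.
#' @param width window width in frames (>= 1).
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, width) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + (width - 1L - half))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Maximal formed runs, merging gaps of duration <= tol (ns): a gap of g
## unformed frames lasts g*dt and, when absorbed, its frames count toward
## the merged event (the event spans first to last formed frame).
contact_events <- function(formed, dt, tol) {
  formed <- as.logical(as.vector(formed))
  if (!any(formed)) return(list(durations = numeric()))
  r <- rle(formed)
  vals <- r$values; lens <- r$lengths
  durations <- numeric(); cur <- 0L; pending_gap <- 0L
  for (i in seq_along(vals)) {
    if (vals[i]) {
      if (cur > 0L) cur <- cur + pending_gap
      pending_gap <- 0L
      cur <- cur + lens[i]
    } else if (cur > 0L) {
      if (lens[i] * dt <= tol) {
        pending_gap <- lens[i]
      } else {
        durations <- c(durations, cur * dt)
        cur <- 0L; pending_gap <- 0L
      }
    }
  }
  if (cur > 0L) durations <- c(durations, cur * dt)
  list(durations = durations)
}

#' Mean H-bond lifetime of a contact series
#'
#' Mean duration of maximal formed runs, where interruptions not exceeding
#' `gap_tolerance` are absorbed into the surrounding event
#' (continuous-with-tolerance estimator). Monotone non-decreasing in the
#' tolerance. With no formed frame the lifetime is 0, with a warning.
#'
#' @param series a `qw_contact_series` (or logical vector with `dt` given).
#' @param gap_tolerance ns; default the series' own tolerance (one frame).
#' @param dt frame spacing, only when `series` is a bare logical vector.
#' @return mean lifetime in ns.
#' @export
hbond_lifetime <- function(series, gap_tolerance = NULL, dt = NULL) {
  if (is.logical(series)) {
    stopifnot(!is.null(dt))
    formed <- series
    if (is.null(gap_tolerance)) gap_tolerance <- dt
  } else {
    formed <- series$formed; dt <- series$dt
    if (is.null(gap_tolerance)) gap_tolerance <- series$gap_tolerance
  }
  if (!any(formed)) {
    warning("no formed frames; lifetime is 0")
    return(0)
  }
  mean(contact_events(formed, dt, gap_tolerance)$durations)
}

#' Hydration-count profile around a centre
#'
#' Per-frame number of distinct water oxygens within `cutoff` of any centre
#' atom, with min/median/max summary.
#'
#' @param traj a `qw_trajectory`.
#' @param center integer atom indices of the centre selection.
#' @param waters water-oxygen indices; defaults to all waters.
#' @param cutoff nm (default 0.35, H-bond distance).
#' @return a `qw_hydration`: list(counts, summary = c(min, median, max)).
#' @export
hydration_counts <- function(traj, center, waters = water_indices(traj),
                             cutoff = 0.35) {
  stopifnot(cutoff > 0)
  if (length(waters) == 0L) stop("empty water set", call. = FALSE)
  nfr <- dim(traj$coords)[1]
  counts <- vapply(seq_len(nfr), function(f) {
    xyz <- frame_coords(traj, f)
    d <- min_dist_to_group(xyz[center, , drop = FALSE],
                           xyz[waters, , drop = FALSE], traj$box)
    sum(d < cutoff)
  }, numeric(1))
  structure(list(counts = as.integer(counts),
                 summary = c(min = min(counts), median = stats::median(counts),
                             max = max(counts))),
            class = "qw_hydration")
}
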