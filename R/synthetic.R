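## Synthetic generators. These stand in for the microsecond-scale MD
## trajectories and the curated experimental ensemble: they produce inputs
## with the statistical structure each analysis stage assumes (Boltzmann
## torsional sampling with or without a well-tempered bias, two-state
## telegraph contact dynamics with known rates, coordinate ensembles with
## planted chi angles and water placements, alignments with planted column
## frequencies), so every parameter-recovery test has a known truth.

#' Define a 1D potential for the torsional samplers
#'
#' @param U vectorised function of the CV returning energy in kJ/mol.
#' @param domain length-2 range of the CV (default the torsional circle in
#'   radians).
#' @param periodic is the CV periodic over the domain?
#' @param kT thermal energy (default 310 K).
#' @return a `qw_potential`.
#' @export
potential_spec <- function(U, domain = c(-pi, pi), periodic = TRUE,
                           kT = kT_at(310)) {
  stopifnot(is.function(U), length(domain) == 2L, domain[2] > domain[1],
            kT > 0)
  structure(list(U = U, domain = domain, periodic = periodic, kT = kT),
            class = "qw_potential")
}

## linear interpolation on a uniform grid (scalar x), grid over [lo, hi]
grid_interp <- function(x, lo, h, gy) {
  ng <- length(gy)
  t <- (x - lo) / h
  i <- floor(t)
  i <- min(max(i, 0), ng - 2L)
  f <- t - i
  gy[i + 1L] * (1 - f) + gy[i + 2L] * f
}

wrap_domain <- function(s, lo, hi) {
  w <- hi - lo
  s - w * floor((s - lo) / w)
}

## Shared Metropolis core. bias_grid is modified in the enclosing
## environment by the deposit callback (NULL for unbiased runs).
metropolis_run <- function(spec, n, step, s0, u_grid, lo, h,
                           bias_env = NULL, stride = NULL, h0 = NULL,
                           gamma = NULL, sigma = NULL) {
  hi <- spec$domain[2]
  kT <- spec$kT
  ng <- length(u_grid)
  s <- s0
  es <- grid_interp(s, lo, h, u_grid)
  vs <- if (!is.null(bias_env)) grid_interp(s, lo, h, bias_env$v_grid) else 0
  out <- numeric(n)
  prop <- stats::rnorm(n, 0, step)
  acc <- stats::runif(n)
  n_acc <- 0L
  grid_x <- seq(lo, hi, length.out = ng)
  for (i in seq_len(n)) {
    cand <- s + prop[i]
    if (spec$periodic) cand <- wrap_domain(cand, lo, hi)
    if (cand >= lo && cand <= hi) {
      ec <- grid_interp(cand, lo, h, u_grid)
      vc <- if (!is.null(bias_env)) grid_interp(cand, lo, h, bias_env$v_grid)
            else 0
      if (acc[i] < exp(-((ec + vc) - (es + vs)) / kT)) {
        s <- cand; es <- ec; vs <- vc; n_acc <- n_acc + 1L
      }
    }
    if (!is.null(bias_env) && i %% stride == 0L) {
      ## well-tempered deposition at the current CV value
      v_here <- grid_interp(s, lo, h, bias_env$v_grid)
      hk <- h0 * exp(-v_here / ((gamma - 1) * kT))
      d <- grid_x - s
      if (spec$periodic) d <- d - (hi - lo) * round(d / (hi - lo))
      bias_env$v_grid <- bias_env$v_grid + hk * exp(-d^2 / (2 * sigma^2))
      bias_env$centers <- c(bias_env$centers, s)
      bias_env$heights <- c(bias_env$heights, hk)
      vs <- grid_interp(s, lo, h, bias_env$v_grid)
    }
    out[i] <- s
  }
  list(values = out, acceptance = n_acc / n, state = s)
}

## Tune the proposal width toward 30-50% acceptance with short pilot runs.
tune_step <- function(spec, u_grid, lo, h, s0, step0) {
  step <- step0
  for (it in 1:12) {
    pilot <- metropolis_run(spec, 400L, step, s0, u_grid, lo, h)
    a <- pilot$acceptance
    if (a >= 0.3 && a <= 0.5) break
    step <- step * if (a > 0.5) 1.6 else 0.6
  }
  step
}

sampler_grids <- function(spec, n_grid = 2048L) {
  lo <- spec$domain[1]; hi <- spec$domain[2]
  grid_x <- seq(lo, hi, length.out = n_grid)
  list(lo = lo, h = grid_x[2] - grid_x[1], u = spec$U(grid_x), x = grid_x)
}

#' Metropolis sampling of a 1D potential
#'
#' Discrete-time Metropolis samples from exp(-U/kT). The proposal width is
#' auto-tuned to 30-50% acceptance on short pilot runs; a fixed seed makes
#' the whole output reproducible.
#'
#' @param spec a `qw_potential`.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param step0 initial proposal width (CV units).
#' @param s0 initial CV value (default domain midpoint).
#' @return a `qw_torsion_series`: list(values, kT, acceptance).
#' @export
sample_potential <- function(spec, n, seed = 1L, step0 = 0.5, s0 = NULL) {
  stopifnot(n >= 1L)
  set.seed(seed)
  g <- sampler_grids(spec)
  if (is.null(s0)) s0 <- mean(spec$domain)
  step <- tune_step(spec, g$u, g$lo, g$h, s0, step0)
  if (!is.finite(step) || step <= 0) stop("divergent step size", call. = FALSE)
  run <- metropolis_run(spec, n, step, s0, g$u, g$lo, g$h)
  structure(list(values = run$values, kT = spec$kT,
                 acceptance = run$acceptance, step = step),
            class = "qw_torsion_series")
}

#' Well-tempered metadynamics sampling of a 1D potential
#'
#' Metropolis dynamics under U + V(s, t), where V accumulates Gaussians
#' deposited every `stride` steps at the current CV value with the
#' well-tempered height schedule h_k = h0 exp(-V(s_k) / ((gamma - 1) kT)).
#' Defaults mirror the production setup of the underlying study: initial
#' height 0.6 kJ/mol, width 0.4 (rad, for torsional CVs), bias factor 15.
#' Returns everything the reweighting stage needs: the samples, the final
#' accumulated bias evaluated at each sample, and the bias itself.
#'
#' @param spec a `qw_potential`.
#' @param n number of samples.
#' @param h0 initial Gaussian height, kJ/mol.
#' @param sigma Gaussian width, CV units.
#' @param gamma bias factor (> 1).
#' @param stride deposition interval in sampler steps.
#' @param seed,step0,s0 as in [sample_potential()].
#' @return list(values, bias_at_samples, bias = list(centers, heights,
#'   sigma, gamma, v_grid, grid_x), kT, acceptance).
#' @export
sample_metadynamics <- function(spec, n, h0 = 0.6, sigma = 0.4, gamma = 15,
                                stride = 500L, seed = 1L, step0 = 0.5,
                                s0 = NULL) {
  stopifnot(n >= 1L, h0 > 0, sigma > 0, stride >= 1L)
  if (gamma <= 1) stop("bias factor gamma must exceed 1", call. = FALSE)
  set.seed(seed)
  g <- sampler_grids(spec)
  if (is.null(s0)) s0 <- mean(spec$domain)
  step <- tune_step(spec, g$u, g$lo, g$h, s0, step0)
  bias_env <- new.env(parent = emptyenv())
  bias_env$v_grid <- numeric(length(g$u))
  bias_env$centers <- numeric()
  bias_env$heights <- numeric()
  run <- metropolis_run(spec, n, step, s0, g$u, g$lo, g$h,
                        bias_env = bias_env, stride = as.integer(stride),
                        h0 = h0, gamma = gamma, sigma = sigma)
  vals <- run$values
  bias_at <- vapply(vals, grid_interp, numeric(1),
                    lo = g$lo, h = g$h, gy = bias_env$v_grid)
  structure(list(values = vals, bias_at_samples = bias_at,
                 bias = list(centers = bias_env$centers,
                             heights = bias_env$heights, sigma = sigma,
                             gamma = gamma, v_grid = bias_env$v_grid,
                             grid_x = g$x),
                 kT = spec$kT, acceptance = run$acceptance, step = step),
            class = "qw_metad_series")
}

#' Two-state telegraph contact process
#'
#' Discrete-time Markov chain on {unformed, formed} with per-frame switch
#' probabilities k_on dt and k_off dt; its stationary occupancy is
#' k_on / (k_on + k_off) and the mean formed dwell time 1/k_off. The time
#' step must satisfy dt * max(rate) <= 0.1 for the discretisation to be
#' faithful.
#'
#' @param k_on,k_off rates in 1/ns.
#' @param dt frame spacing in ns.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return logical vector of per-frame formation with attributes `dt`,
#'   `k_on`, `k_off`.
#' @export
telegraph_series <- function(k_on, k_off, dt, n_frames, seed = 1L) {
  stopifnot(k_on > 0, k_off > 0, dt > 0, n_frames >= 1L)
  if (dt * max(k_on, k_off) > 0.1)
    stop("dt too coarse: dt * max(rate) must be <= 0.1", call. = FALSE)
  set.seed(seed)
  p_on <- k_on * dt; p_off <- k_off * dt
  u <- stats::runif(n_frames)
  x <- logical(n_frames)
  state <- u[1] < k_on / (k_on + k_off)  # start from the stationary law
  x[1] <- state
  for (i in 2:n_frames) {
    state <- if (state) u[i] >= p_off else u[i] < p_on
    x[i] <- state
  }
  attr(x, "dt") <- dt; attr(x, "k_on") <- k_on; attr(x, "k_off") <- k_off
  x
}

conformer_center <- function(label) {
  switch(label, "t" = 180, "g" = 60, "-g" = -60,
         stop("unknown conformer label ", label, call. = FALSE))
}

## Ideal internal coordinates (nm, degrees) used by the residue builder.
res_build_params <- list(
  N_CA = 0.1458, CA_CB = 0.1530, CB_CG = 0.1520, CG_CD = 0.1520,
  N_CA_CB = 110.5, CA_CB_CG = 114.1, CB_CG_CD = 112.6)

## Build one side chain with planted chi angles at a given origin offset.
## Returns a data.frame of atom rows.
build_residue <- function(resname, resid, chi1, chi2 = NULL, offset,
                          chain = "A") {
  p <- res_build_params
  n <- c(0, 0, 0)
  ca <- c(p$N_CA, 0, 0)
  cb <- place_atom(c(0, 0, 1) + ca, n, ca, p$CA_CB, p$N_CA_CB, 57.3)
  ## chi1 quartet N-CA-CB-CG
  cg <- place_atom(n, ca, cb, p$CB_CG, p$CA_CB_CG, chi1)
  atoms <- list(N = n, CA = ca, CB = cb, CG = cg)
  if (!is.null(chi2)) {
    nxt <- switch(toupper(resname), GLU = "CD", TYR = "CD1", HIS = "ND1",
                  ASP = "OD1", "CD")
    atoms[[nxt]] <- place_atom(ca, cb, cg, p$CG_CD, p$CB_CG_CD, chi2)
  }
  if (toupper(resname) == "TYR") {
    ## phenolic oxygen: fixed placement down the ring direction
    atoms$OH <- cg + c(0.42, 0, 0)
  }
  do.call(rbind, lapply(names(atoms), function(a)
    data.frame(chain = chain, resid = resid, resname = toupper(resname),
               atom = a,
               x = atoms[[a]][1] + offset[1], y = atoms[[a]][2] + offset[2],
               z = atoms[[a]][3] + offset[3], stringsAsFactors = FALSE)))
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    nv <- sqrt(sum(v * v))
    if (nv > 1e-8) return(v / nv)
  }
}

random_rotation <- function() {
  ## QR of a random Gaussian matrix, determinant fixed to +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic Qo-site model ensemble with planted geometry
#'
#' Builds single-chain models containing the surveyed side chains (Y147,
#' E295, Y297, optionally H276/D278), a Rieske H152 epsilon nitrogen and a
#' quinone head group, with side-chain chi angles planted at requested
#' conformers (or explicit angles), waters planted at exact distances from
#' a centre atom, and an optional rigid-body rotation + translation of the
#' whole model. Planted chi angles survive the build to within 0.1 degree
#' and round-trip through the survey stage.
#'
#' @param tuples character matrix (n_models x 4) of conformer labels for
#'   (Y147 chi1, E295 chi1, E295 chi2, Y297 chi1), or numeric matrix of
#'   explicit angles in degrees.
#' @param extra_chi optional named list of numeric vectors (length
#'   n_models) planting chi1 angles for additional residues, e.g.
#'   `list(H276 = ..., D278 = ...)`.
#' @param n_waters_near,near_radius waters planted at exactly
#'   `near_radius` nm from the centre atom (Y147 CG).
#' @param n_waters_far,far_radius waters planted farther out.
#' @param qbound optional length-2 numeric `c(h152_o4, y147_o1)` planting
#'   the two Q-bound distances in nm.
#' @param jitter rigid-body: random rotation plus translation of up to
#'   `jitter` nm applied to each whole model (0 = exact planted frame).
#' @param seed RNG seed.
#' @param dir if non-NULL, write one PDB file per model into `dir` and
#'   return the file paths; otherwise return `qw_model` objects.
#' @return list of `qw_model`, or character vector of PDB paths.
#' @export
make_model_ensemble <- function(tuples, extra_chi = NULL, n_waters_near = 0,
                                near_radius = 0.3, n_waters_far = 0,
                                far_radius = 0.7, qbound = NULL, jitter = 0,
                                seed = 1L, dir = NULL) {
  if (is.data.frame(tuples)) tuples <- as.matrix(tuples)
  if (!is.matrix(tuples) || ncol(tuples) != 4L)
    stop("tuples must be an n x 4 matrix", call. = FALSE)
  set.seed(seed)
  n_models <- nrow(tuples)
  out <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    ang <- if (is.numeric(tuples)) wrap_angle(tuples[m, ])
           else vapply(tuples[m, ], conformer_center, numeric(1))
    atoms <- rbind(
      build_residue("TYR", 147, chi1 = ang[1], offset = c(0, 0, 0)),
      build_residue("GLU", 295, chi1 = ang[2], chi2 = ang[3],
                    offset = c(2, 0, 0)),
      build_residue("TYR", 297, chi1 = ang[4], offset = c(0, 2, 0)))
    if (!is.null(extra_chi)) {
      off <- c(2, 2, 0)
      for (nm in names(extra_chi)) {
        rtype <- switch(substr(nm, 1, 1), H = "HIS", D = "ASP", "HIS")
        resid <- as.integer(sub("^[A-Z]", "", nm))
        atoms <- rbind(atoms, build_residue(rtype, resid,
                                            chi1 = extra_chi[[nm]][m],
                                            offset = off))
        off <- off + c(0, 0, 2)
      }
    }
    ## H152 (Rieske, chain B) epsilon nitrogen and the quinone head
    if (!is.null(qbound)) {
      ne2 <- c(-2, -2, 0)
      yoh <- as.numeric(atoms[atoms$resid == 147 & atoms$atom == "OH",
                              c("x", "y", "z")])
      o4 <- ne2 + qbound[1] * random_unit()
      o1 <- yoh + qbound[2] * random_unit()
      atoms <- rbind(atoms,
        data.frame(chain = "B", resid = 152, resname = "HIS", atom = "NE2",
                   x = ne2[1], y = ne2[2], z = ne2[3]),
        data.frame(chain = "A", resid = 500, resname = "UQ6",
                   atom = c("O1", "O4"),
                   x = c(o1[1], o4[1]), y = c(o1[2], o4[2]),
                   z = c(o1[3], o4[3])))
    }
    ## planted waters around the Y147 CG centre
    centre <- as.numeric(atoms[atoms$resid == 147 & atoms$atom == "CG",
                               c("x", "y", "z")])
    nw <- n_waters_near + n_waters_far
    if (nw > 0) {
      wx <- t(vapply(seq_len(nw), function(i) {
        r <- if (i <= n_waters_near) near_radius else far_radius
        centre + r * random_unit()
      }, numeric(3)))
      atoms <- rbind(atoms,
        data.frame(chain = "W", resid = 1000 + seq_len(nw), resname = "HOH",
                   atom = "O", x = wx[, 1], y = wx[, 2], z = wx[, 3]))
    }
    if (jitter > 0) {
      rot <- random_rotation()
      tr <- stats::runif(3, -jitter, jitter)
      xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
      atoms$x <- xyz[, 1] + tr[1]
      atoms$y <- xyz[, 2] + tr[2]
      atoms$z <- xyz[, 3] + tr[3]
    }
    out[[m]] <- structure_model(sprintf("synthetic_%03d", m), atoms,
                                method = "synthetic")
  }
  if (is.null(dir)) return(out)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(out, function(mod) {
    path <- file.path(dir, paste0(mod$model_id, ".pdb"))
    write_model_pdb(mod, path)
    path
  }, character(1))
}

#' Write a structure model as a PDB file
#'
#' @param model a `qw_model`.
#' @param path output .pdb path.
#' @return invisibly, the path.
#' @export
write_model_pdb <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))) * 10,
                   type = ifelse(at$resname %in% c(water_resnames(), "UQ6"),
                                 "HETATM", "ATOM"),
                   resno = at$resid, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$atom,
                   chain = at$chain, o = at$occ, b = rep(0, nrow(at)))
  invisible(path)
}

#' Residue map matching the synthetic ensembles
#'
#' @return a `qw_residue_map` with a wildcard entry covering every
#'   synthetic model.
#' @export
synthetic_residue_map <- function() {
  residue_map(data.frame(
    model_id = "*",
    role = c("Y147", "E295", "Y297", "H276", "D278", "H152", "Q_head"),
    chain = c("A", "A", "A", "A", "A", "B", "A"),
    resid = c(147, 295, 297, 276, 278, 152, 500),
    stringsAsFactors = FALSE))
}

#' Generate an alignment with planted column frequencies
#'
#' Multinomial draws per column with a gap-free reference row (the
#' per-column consensus). Optional per-row gap fractions replace a random
#' subset of columns with gaps.
#'
#' @param n_rows sequences to draw (excluding the reference).
#' @param freqs list, one element per column: named probability vector over
#'   one-letter codes, summing to 1.
#' @param gap_fractions optional numeric vector (length `n_rows`) of
#'   per-row gap fractions.
#' @param ref_id reference row id.
#' @param ref_start reference numbering of the first column.
#' @param seed RNG seed.
#' @param path if non-NULL, also write the alignment as FASTA.
#' @return a `qw_alignment`.
#' @export
make_msa <- function(n_rows, freqs, gap_fractions = NULL, ref_id = "ref",
                     ref_start = 1L, seed = 1L, path = NULL) {
  stopifnot(n_rows >= 1L, length(freqs) >= 1L)
  for (f in freqs)
    if (abs(sum(f) - 1) > 1e-8 || any(f < 0))
      stop("each column frequency vector must be non-negative and sum to 1",
           call. = FALSE)
  set.seed(seed)
  ncol_ <- length(freqs)
  m <- matrix("", n_rows, ncol_)
  for (j in seq_len(ncol_))
    m[, j] <- sample(names(freqs[[j]]), n_rows, replace = TRUE,
                     prob = freqs[[j]])
  if (!is.null(gap_fractions)) {
    stopifnot(length(gap_fractions) == n_rows)
    for (i in seq_len(n_rows)) {
      k <- round(gap_fractions[i] * ncol_)
      if (k > 0) m[i, sample.int(ncol_, k)] <- "-"
    }
  }
  ref <- vapply(freqs, function(f) names(f)[which.max(f)], character(1))
  seqs <- c(stats::setNames(paste(ref, collapse = ""), ref_id),
            stats::setNames(apply(m, 1L, paste, collapse = ""),
                            sprintf("seq%04d", seq_len(n_rows))))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  }
  alignment(seqs, reference_id = ref_id, ref_start = ref_start)
}
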