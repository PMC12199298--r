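#' Thermal energy kT in kJ/mol at a temperature
#'
#' Gas constant times temperature; at the simulation temperature of 310 K
#' this is 2.577 kJ/mol.
#'
#' @param temperature K.
#' @return kT in kJ/mol.
#' @export
kT_at <- function(temperature = 310) 0.008314462618 * temperature

#' Bundle collective-variable samples with weights
#'
#' @param values numeric vector (1D CV) or two-column matrix (2D CV).
#' @param weights per-frame positive weights; default 1 (unbiased frames).
#' @param kT thermal energy in kJ/mol (default 310 K).
#' @return a `qw_samples`.
#' @export
sample_set <- function(values, weights = NULL, kT = kT_at(310)) {
  if (is.data.frame(values)) values <- as.matrix(values)
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, kT > 0)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be finite and > 0", call. = FALSE)
  structure(list(values = values, weights = weights, kT = kT),
            class = "qw_samples")
}

#' Concatenate sample sets with per-set weight normalisation
#'
#' Biased and unbiased trajectories are combined on an equal-time footing:
#' each set's weights are rescaled to sum to its own frame count before
#' concatenation, so every trajectory contributes in proportion to its
#' length, not to its raw weight mass.
#'
#' @param ... `qw_samples` objects on the same CV and kT.
#' @return a single `qw_samples`.
#' @export
combine_sample_sets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  kT <- sets[[1]]$kT
  vals <- list(); wts <- list()
  for (s in sets) {
    stopifnot(inherits(s, "qw_samples"), isTRUE(all.equal(s$kT, kT)))
    n <- if (is.matrix(s$values)) nrow(s$values) else length(s$values)
    vals[[length(vals) + 1L]] <- s$values
    wts[[length(wts) + 1L]] <- s$weights * n / sum(s$weights)
  }
  values <- if (is.matrix(sets[[1]]$values)) do.call(rbind, vals)
            else unlist(vals)
  sample_set(values, unlist(wts), kT)
}

bin_index <- function(x, edges) {
  ## right-closed bins [e_i, e_{i+1}), last bin closed on both sides
  i <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

#' Weighted histogram over bins
#'
#' Normalised weighted bin probabilities: p_b = sum of in-bin weights over
#' the total in-range weight. Out-of-range samples are dropped from both
#' numerator and denominator.
#'
#' @param samples a `qw_samples`.
#' @param edges bin edges (1D), or list of two edge vectors (2D).
#' @return probabilities: vector (1D) or matrix (2D), summing to 1.
#' @export
weighted_histogram <- function(samples, edges) {
  stopifnot(inherits(samples, "qw_samples"))
  v <- samples$values; w <- samples$weights
  if (is.matrix(v)) {
    stopifnot(is.list(edges), length(edges) == 2L)
    ix <- bin_index(v[, 1], edges[[1]])
    iy <- bin_index(v[, 2], edges[[2]])
    ok <- !is.na(ix) & !is.na(iy)
    if (!any(ok)) stop("all samples fall outside the bin range", call. = FALSE)
    p <- matrix(0, length(edges[[1]]) - 1L, length(edges[[2]]) - 1L)
    for (k in which(ok)) p[ix[k], iy[k]] <- p[ix[k], iy[k]] + w[k]
    return(p / sum(p))
  }
  i <- bin_index(v, edges)
  ok <- !is.na(i)
  if (!any(ok)) stop("all samples fall outside the bin range", call. = FALSE)
  p <- vapply(seq_len(length(edges) - 1L),
              function(b) sum(w[ok][i[ok] == b]), numeric(1))
  p / sum(p)
}

#' Free-energy profile from samples
#'
#' Bins the (possibly reweighted) samples, takes dG_b = -kT log p_b, masks
#' empty bins (never extrapolating across them), and shifts so the minimum
#' over unmasked bins is zero.
#'
#' @param samples a `qw_samples`.
#' @param edges bin edges (1D vector, or list of two for 2D).
#' @return a `qw_fes`: list(edges, centers, dG, se, mask) with dG in kJ/mol;
#'   `mask` is TRUE for empty bins, whose dG is NA.
#' @export
profile_from_samples <- function(samples, edges) {
  p <- weighted_histogram(samples, edges)
  dG <- -samples$kT * log(p)
  dG[!is.finite(dG)] <- NA_real_
  dG <- dG - min(dG, na.rm = TRUE)
  centers <- if (is.list(edges)) lapply(edges, mid_points) else mid_points(edges)
  structure(list(edges = edges, centers = centers, dG = dG,
                 se = array(0, dim = dim(p) %||% length(p)),
                 mask = is.na(dG), kT = samples$kT),
            class = "qw_fes")
}

mid_points <- function(e) (e[-1] + e[-length(e)]) / 2

#' Remove a metadynamics bias by reweighting
#'
#' Final-bias reweighting: frames sampled under an accumulated bias V(s)
#' re-enter the unbiased ensemble with weights w_i proportional to
#' exp(+V(s_i)/kT), where V is the final accumulated bias evaluated at each
#' frame's CV value. A constant bias yields uniform weights, so the
#' unbiased pipeline is recovered exactly when V = 0.
#'
#' @param values CV values per frame.
#' @param bias_at_samples final bias V(s_i) in kJ/mol, same length.
#' @param kT kJ/mol.
#' @return a `qw_samples` with reweighting weights.
#' @export
reweight_metadynamics <- function(values, bias_at_samples, kT = kT_at(310)) {
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (length(bias_at_samples) != n)
    stop("bias vector length must match values", call. = FALSE)
  if (any(!is.finite(bias_at_samples)))
    stop("non-finite bias values", call. = FALSE)
  ## subtract the max for numerical stability; weights are defined up to scale
  w <- exp((bias_at_samples - max(bias_at_samples)) / kT)
  sample_set(values, w, kT)
}

#' Average replica profiles with standard errors
#'
#' Per-bin mean dG over replicas, with SE the sample standard deviation over
#' replicas divided by sqrt(n). A bin masked (empty) in any replica is
#' masked in the output. With n = 2 replicas the SE has a single degree of
#' freedom and should be read qualitatively.
#'
#' @param profiles list of `qw_fes` on identical edges.
#' @return a combined `qw_fes`.
#' @export
combine_replicas <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  e1 <- profiles[[1]]$edges
  for (p in profiles[-1]) {
    same <- if (is.list(e1)) isTRUE(all.equal(e1, p$edges))
            else isTRUE(all.equal(as.numeric(e1), as.numeric(p$edges)))
    if (!same) stop("replica profiles must share identical bin edges",
                    call. = FALSE)
  }
  n <- length(profiles)
  dGs <- lapply(profiles, function(p) p$dG)
  arr <- simplify2array(dGs)
  dims <- dim(profiles[[1]]$dG) %||% length(profiles[[1]]$dG)
  marg <- length(dim(arr))
  mean_dG <- apply(arr, seq_len(marg - 1L), mean)
  se <- apply(arr, seq_len(marg - 1L), stats::sd) / sqrt(n)
  mask <- apply(simplify2array(lapply(profiles, function(p) p$mask)),
                seq_len(marg - 1L), any)
  mean_dG[mask] <- NA_real_
  se[mask] <- NA_real_
  mean_dG <- mean_dG - min(mean_dG, na.rm = TRUE)
  structure(list(edges = e1, centers = profiles[[1]]$centers, dG = mean_dG,
                 se = se, mask = mask, kT = profiles[[1]]$kT,
                 n_replicas = n),
            class = "qw_fes")
}

#' @export
print.qw_fes <- function(x, ...) {
  nb <- length(x$dG)
  cat(sprintf("Free-energy profile: %d bins (%d masked), range 0 to %.2f kJ/mol\n",
              nb, sum(x$mask), max(x$dG, na.rm = TRUE)))
  invisible(x)
}

#' Write a free-energy profile as TSV
#'
#' @param fes a `qw_fes` (1D).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fes <- function(fes, path) {
  stopifnot(!is.list(fes$edges))
  df <- data.frame(center = fes$centers, dG_kJ_mol = fes$dG,
                   se_kJ_mol = as.numeric(fes$se), masked = fes$mask)
  con <- file(path, "w")
  writeLines(c("# qowire free-energy profile",
               sprintf("# kT = %.4f kJ/mol; empty bins masked, min-shifted to 0",
                       fes$kT)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Evaluate an accumulated Gaussian bias
#'
#' V(s) = sum_k h_k exp(-(s - s_k)^2 / (2 sigma^2)); for periodic
#' (angular) CVs the displacement is the minimum image on the period.
#'
#' @param s evaluation points.
#' @param centers deposited Gaussian centres s_k.
#' @param heights deposited heights h_k (kJ/mol).
#' @param sigma Gaussian width (CV units).
#' @param period optional CV period (e.g. 2*pi for torsions in radians).
#' @return bias values in kJ/mol.
#' @export
eval_bias <- function(s, centers, heights, sigma, period = NULL) {
  stopifnot(length(centers) == length(heights))
  v <- numeric(length(s))
  for (k in seq_along(centers)) {
    d <- s - centers[k]
    if (!is.null(period)) d <- d - period * round(d / period)
    v <- v + heights[k] * exp(-d^2 / (2 * sigma^2))
  }
  v
}
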